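#' Published pharmacological preferences for two benchmark targets
#'
#' Literature-reported pharmacological preference values (`w`) and
#' consensus interaction ratios (`ratio`, over 10 known active compounds)
#' for two classical screening benchmark targets: the estrogen receptor
#' alpha agonist site (ERA) and herpes simplex virus type-1 thymidine
#' kinase (TK).  Useful as a worked example for the W >= 0.4 call rule and
#' the ratio >= 0.5 hot-spot rule: ERA has 10 reported pharmacological
#' interactions of which 9 coincide with hot spots (the exception is the
#' L387 hydrogen-bond interaction); TK has 14 of which 8 are hot spots.
#'
#' @param target optionally restrict to `"ERA"` or `"TK"`.
#' @return tibble with columns `target`, `residue`, `resname`, `resno`,
#'   `type` (E/H/V channel), `w` (preference) and `ratio` (consensus
#'   interaction ratio).
#' @export
reference_pharmacology <- function(target = NULL) {
  path <- system.file("extdata", "reference_era_tk.tsv", package = "pharmint",
                      mustWork = TRUE)
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    target = readr::col_character(), residue = readr::col_character(),
    resname = readr::col_character(), resno = readr::col_integer(),
    type = readr::col_character(), w = readr::col_double(),
    ratio = readr::col_double()))
  if (!is.null(target)) {
    tbl <- dplyr::filter(tbl, .data$target == !!target)
  }
  tbl
}
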