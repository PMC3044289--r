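#' Default profile thresholds (kcal/mol)
#'
#' A compound-group cell is "interacting" when its channel energy meets the
#' threshold: at or below -2.5 for the electrostatic and hydrogen-bonding
#' channels (inclusive boundary), strictly below -4 for van der Waals.
#'
#' @return named list `E`, `H`, `V`.
#' @export
profile_thresholds <- function() {
  list(E = -2.5, H = -2.5, V = -4)
}

#' Build a binary interaction profile from an energy decomposition
#'
#' Produces the N x 2K binary matrix for one interaction channel: rows are
#' compounds (input order), columns the binding-site residue groups in site
#' order.  `p[i, j] = 1` when the channel energy of compound `i` at group
#' `j` meets the channel threshold (`<=` for E and H, `<` for V).
#'
#' @param decomp an `energy_decomposition` tibble (see [batch_decompose()]).
#' @param site the `binding_site` the decomposition was computed against.
#' @param type `"E"`, `"H"` or `"V"`.
#' @param thresholds named list of channel thresholds
#'   (default [profile_thresholds()]).
#' @return an object of class `interaction_profile`: list with `type`,
#'   `matrix` (integer, dimnames = compounds x group labels), `threshold`.
#' @export
build_profile <- function(decomp, site, type = c("E", "H", "V"),
                          thresholds = profile_thresholds()) {
  type <- match.arg(type)
  thr <- thresholds[[type]]
  dd <- dplyr::filter(tibble::as_tibble(decomp), .data$type == !!type)
  pose_key <- dplyr::distinct(dd, .data$compound_id, .data$pose_index)
  if (anyDuplicated(pose_key$compound_id)) {
    rows <- paste0(pose_key$compound_id, "#", pose_key$pose_index)
    key <- paste0(dd$compound_id, "#", dd$pose_index)
  } else {
    rows <- pose_key$compound_id
    key <- dd$compound_id
  }
  cols <- site$groups$label
  m <- matrix(0L, nrow = length(rows), ncol = length(cols),
              dimnames = list(rows, cols))
  hit <- if (type == "V") dd$energy < thr else dd$energy <= thr
  m[cbind(match(key, rows), match(dd$label, cols))] <- as.integer(hit)
  new_interaction_profile(type, m, thr)
}

new_interaction_profile <- function(type, matrix, threshold = NA_real_) {
  storage.mode(matrix) <- "integer"
  if (any(!matrix %in% c(0L, 1L))) abort("profile entries must be 0/1")
  if (anyDuplicated(rownames(matrix))) abort("profile row labels must be unique")
  structure(list(type = type, matrix = matrix, threshold = threshold),
            class = "interaction_profile")
}

#' @export
print.interaction_profile <- function(x, ...) {
  cat("<interaction_profile ", x$type, "> ", nrow(x$matrix), " compounds x ",
      ncol(x$matrix), " residue groups, density ",
      signif(mean(x$matrix), 3), "\n", sep = "")
  invisible(x)
}

#' Tidy an interaction profile into long format
#' @param x an `interaction_profile`.
#' @param ... ignored.
#' @return tibble with `compound_id`, `group`, `type`, `value`.
#' @method tidy interaction_profile
#' @export
tidy.interaction_profile <- function(x, ...) {
  tibble::tibble(
    compound_id = rep(rownames(x$matrix), times = ncol(x$matrix)),
    group = rep(colnames(x$matrix), each = nrow(x$matrix)),
    type = x$type,
    value = as.integer(x$matrix)
  )
}

#' One-row summary of an interaction profile
#' @param x an `interaction_profile`.
#' @param ... ignored.
#' @return one-row tibble with dimensions, density and threshold.
#' @method glance interaction_profile
#' @export
glance.interaction_profile <- function(x, ...) {
  tibble::tibble(type = x$type, n_compounds = nrow(x$matrix),
                 n_groups = ncol(x$matrix), density = mean(x$matrix),
                 threshold = x$threshold)
}

#' Write / read an interaction profile as TSV
#'
#' Lossless round trip: header = `compound_id` + column labels, one row per
#' compound, binary cells.  Reading validates that every cell is 0 or 1 and
#' errors naming the offending cell otherwise.
#'
#' @param profile an `interaction_profile`.
#' @param path file path.
#' @param type channel tag stored in the object on read (default from the
#'   file name suffix `_E`/`_H`/`_V` if present, else `"H"`).
#' @return `path` (write) or an `interaction_profile` (read).
#' @export
write_profile <- function(profile, path) {
  df <- tibble::as_tibble(profile$matrix, .name_repair = "minimal")
  ids <- rownames(profile$matrix) %||% character(0)
  df <- dplyr::bind_cols(tibble::tibble(compound_id = ids), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path, type = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    compound_id = readr::col_character(), .default = readr::col_double()))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$compound_id
  bad <- which(!(m %in% c(0, 1)))
  if (length(bad) > 0) {
    i <- ((bad[1] - 1) %% nrow(m)) + 1
    j <- ((bad[1] - 1) %/% nrow(m)) + 1
    abort(paste0("non-binary value ", m[bad[1]], " at compound ",
                 rownames(m)[i], ", column ", colnames(m)[j]))
  }
  if (is.null(type)) {
    hit <- regmatches(path, regexpr("_([EHV])\\.tsv$", path))
    type <- if (length(hit) == 1) sub("_([EHV])\\.tsv$", "\\1", hit) else "H"
  }
  new_interaction_profile(type, m)
}

#' Heatmap of an interaction profile
#'
#' Compounds on the y axis, residue groups on the x axis; green cells mark
#' present interactions, black cells absent ones.
#'
#' @param object an `interaction_profile`.
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot interaction_profile
#' @export
autoplot.interaction_profile <- function(object, ...) {
  long <- tidy(object)
  long$group <- factor(long$group, levels = colnames(object$matrix))
  long$compound_id <- factor(long$compound_id,
                             levels = rev(rownames(object$matrix)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$compound_id,
                                     fill = factor(.data$value))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`0` = "black", `1` = "green3"),
                               name = "interaction") +
    ggplot2::labs(x = "residue group", y = "compound",
                  title = paste0(object$type, " interaction profile")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Subset profile rows
#' @param profile an `interaction_profile`.
#' @param compounds compound ids or row indices to keep.
#' @return an `interaction_profile` with the selected rows.
#' @export
subset_profile <- function(profile, compounds) {
  new_interaction_profile(profile$type,
                          profile$matrix[compounds, , drop = FALSE],
                          profile$threshold)
}
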