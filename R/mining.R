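# Pharmacological-interaction mining.
#
# A profile column is "pharmacologically conserved" when its interaction
# frequency across the screening library is anomalously high relative to a
# shuffle null: the observed column frequency f_j is z-scored against the
# mean and standard deviation of the same frequency over randomly shuffled
# profiles, the z-scores are normalised by the largest z of the channel
# (W_j = z_j / z_max, so the best column scores exactly 1), and columns with
# W_j >= 0.4 are called pharmacological.

#' Shuffle null model for profile column frequencies
#'
#' Estimates, per profile column, the mean and standard deviation of the
#' column interaction frequency over `n_shuffles` randomly shuffled
#' profiles.  The default scheme permutes all N x 2K cells of the matrix
#' uniformly (equivalently: redistributes the observed 1-cells over all
#' positions without replacement), which conserves the total number of
#' interactions and makes columns exchangeable under the null.  `"rows"`
#' permutes each compound's row independently (conserves per-compound
#' interaction counts); `"columns"` permutes within columns, which leaves
#' every column frequency unchanged and is only useful as a degeneracy
#' check.
#'
#' @param profile an `interaction_profile`.
#' @param n_shuffles number of shuffled profiles (default 1000).
#' @param seed RNG seed (default 33); the generator state is restored on
#'   exit.
#' @param scheme `"matrix"` (default), `"rows"` or `"columns"`.
#' @return an object of class `null_model`: tibble with `group`, `mu`,
#'   `sigma` plus attributes `n_shuffles`, `seed`, `scheme`, `type`,
#'   `n_compounds`, `n_ones`.
#' @export
shuffle_null <- function(profile, n_shuffles = 1000, seed = 33,
                         scheme = c("matrix", "rows", "columns")) {
  scheme <- match.arg(scheme)
  if (n_shuffles < 1) abort("n_shuffles must be >= 1")
  m <- profile$matrix
  n <- nrow(m); k2 <- ncol(m); total <- n * k2
  n_ones <- sum(m)
  if (n_ones == 0 || n_ones == total) {
    warn(paste0("degenerate profile (all ", ifelse(n_ones == 0, 0, 1),
                "): null standard deviations are zero"))
  }
  freqs <- withr::with_seed(seed, switch(scheme,
    matrix = {
      f <- matrix(0, nrow = n_shuffles, ncol = k2)
      if (n_ones > 0 && n_ones < total) {
        for (s in seq_len(n_shuffles)) {
          # positions of the 1-cells after a uniform permutation of all
          # cells = a uniform size-n_ones subset of the cell indices
          pos <- sample.int(total, n_ones)
          f[s, ] <- tabulate((pos - 1L) %/% n + 1L, nbins = k2) / n
        }
      } else {
        f[] <- rep(colMeans(m), each = n_shuffles)
      }
      f
    },
    rows = {
      f <- matrix(0, nrow = n_shuffles, ncol = k2)
      row_ones <- rowSums(m)
      for (s in seq_len(n_shuffles)) {
        counts <- integer(k2)
        for (i in seq_len(n)) {
          if (row_ones[i] == 0) next
          cols <- if (row_ones[i] == k2) seq_len(k2) else
            sample.int(k2, row_ones[i])
          counts[cols] <- counts[cols] + 1L
        }
        f[s, ] <- counts / n
      }
      f
    },
    columns = {
      matrix(rep(colMeans(m), each = n_shuffles), nrow = n_shuffles)
    }
  ))
  mu <- colMeans(freqs)
  sigma <- apply(freqs, 2, sd)
  out <- tibble::tibble(group = colnames(m), mu = mu, sigma = sigma)
  structure(out, class = c("null_model", class(out)),
            n_shuffles = as.integer(n_shuffles), seed = seed,
            scheme = scheme, type = profile$type, n_compounds = n,
            n_ones = n_ones)
}

#' Compute pharmacological preferences from a profile and its null model
#'
#' For each column: the observed interaction frequency
#' `f_j = mean_i p[i, j]`, its z-score against the null
#' (`z_j = (f_j - mu_j) / sigma_j`) and the normalised preference
#' `W_j = z_j / z_max` where `z_max` is the largest z-score of the channel,
#' so the most conserved column scores exactly 1.  Degenerate columns
#' (`sigma_j = 0`) get `W_j = 0` with a warning; when no column exceeds the
#' null (`z_max <= 0`) all preferences are 0.
#'
#' @param profile an `interaction_profile`.
#' @param null a `null_model` built from a profile of the same shape.
#' @return a `preference_table`: tibble with `type`, `group`, `chain`,
#'   `resname`, `resno`, `part` (where the labels parse), `f`, `mu`,
#'   `sigma`, `z`, `w`; attribute `z_max`.
#' @export
compute_preferences <- function(profile, null) {
  m <- profile$matrix
  if (!identical(colnames(m), null$group)) {
    abort("profile and null model have different columns")
  }
  f <- colMeans(m)
  sigma <- null$sigma; mu <- null$mu
  z <- ifelse(sigma > 0, (f - mu) / sigma, NA_real_)
  if (any(sigma == 0)) {
    warn(paste0(sum(sigma == 0), " column(s) with zero null variance; ",
                "their preferences are set to 0"))
  }
  finite_z <- z[!is.na(z)]
  z_max <- if (length(finite_z) > 0) max(finite_z) else NA_real_
  if (!is.na(z_max) && z_max > 0) {
    w <- ifelse(is.na(z), 0, z / z_max)
  } else {
    if (!is.na(z_max)) warn("largest z-score is not positive; all preferences set to 0")
    w <- rep(0, length(z))
  }
  parsed <- tryCatch(parse_group_label(colnames(m)), error = function(e) NULL)
  out <- tibble::tibble(type = profile$type, group = colnames(m))
  if (!is.null(parsed)) out <- dplyr::bind_cols(out, parsed)
  out$f <- f; out$mu <- mu; out$sigma <- sigma; out$z <- z; out$w <- w
  structure(out, class = c("preference_table", class(out)),
            z_max = z_max, n_compounds = nrow(m),
            n_shuffles = attr(null, "n_shuffles"), seed = attr(null, "seed"))
}

#' Call pharmacological interactions from preferences
#'
#' Adds a logical `call` column: `TRUE` where the pharmacological preference
#' `w` is at or above the threshold (inclusive; default 0.4).  Works on any
#' data frame with a `w` column, so published preference values can be run
#' through the same rule as mined ones.
#'
#' @param prefs a `preference_table` (or any data frame with a `w` column).
#' @param threshold call cutoff on `w` (default 0.4).
#' @return `prefs` with a `call` column.
#' @export
call_pharmacological <- function(prefs, threshold = 0.4) {
  if (!"w" %in% names(prefs)) abort("`prefs` must have a `w` column")
  dplyr::mutate(prefs, call = .data$w >= threshold)
}

#' Mine a profile end to end
#'
#' Convenience wrapper: [shuffle_null()] then [compute_preferences()] then
#' [call_pharmacological()].
#'
#' @inheritParams shuffle_null
#' @inheritParams call_pharmacological
#' @return a called `preference_table`.
#' @export
mine_profile <- function(profile, n_shuffles = 1000, seed = 33,
                         threshold = 0.4,
                         scheme = c("matrix", "rows", "columns")) {
  null <- shuffle_null(profile, n_shuffles = n_shuffles, seed = seed,
                       scheme = match.arg(scheme))
  call_pharmacological(compute_preferences(profile, null),
                       threshold = threshold)
}

#' One-row summary of a preference table
#' @param x a `preference_table`.
#' @param ... ignored.
#' @return one-row tibble with channel, sizes, `z_max` and the number of
#'   called interactions (when calls are present).
#' @method glance preference_table
#' @export
glance.preference_table <- function(x, ...) {
  tibble::tibble(
    type = x$type[1],
    n_groups = nrow(x),
    n_compounds = attr(x, "n_compounds") %||% NA_integer_,
    n_shuffles = attr(x, "n_shuffles") %||% NA_integer_,
    z_max = attr(x, "z_max") %||% NA_real_,
    n_called = if ("call" %in% names(x)) sum(x$call) else NA_integer_
  )
}

#' Bar chart of pharmacological preferences
#'
#' One bar per residue group, coloured by call status, with the call
#' threshold drawn as a dashed line.
#'
#' @param object a called `preference_table`.
#' @param threshold threshold line position (default 0.4).
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot preference_table
#' @export
autoplot.preference_table <- function(object, threshold = 0.4, ...) {
  df <- tibble::as_tibble(object)
  if (!"call" %in% names(df)) df$call <- df$w >= threshold
  df$group <- factor(df$group, levels = df$group[order(-df$w)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$w,
                                   fill = .data$call)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "forestgreen",
                                          `FALSE` = "grey60"),
                               name = "pharmacological") +
    ggplot2::labs(x = "residue group", y = "preference W") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Consensus interaction ratios and hot spots over an active set
#'
#' For a profile restricted to known active compounds, the consensus
#' interaction ratio of a column is the fraction of actives showing the
#' interaction; a residue group is a hot spot when the ratio is at or above
#' the threshold (inclusive; default 0.5).
#'
#' @param active_profile an `interaction_profile` whose rows are the known
#'   actives (any N >= 1).
#' @param threshold hot-spot cutoff on the ratio (default 0.5).
#' @return a `consensus_table`: tibble with `type`, `group`, `ratio`,
#'   `hot_spot`.
#' @export
consensus_ratio <- function(active_profile, threshold = 0.5) {
  m <- active_profile$matrix
  if (nrow(m) == 0) abort("active profile has no rows")
  out <- tibble::tibble(type = active_profile$type, group = colnames(m),
                        ratio = colMeans(m))
  out$hot_spot <- out$ratio >= threshold
  structure(out, class = c("consensus_table", class(out)),
            n_actives = nrow(m), threshold = threshold)
}

#' Compare called pharmacological interactions with consensus hot spots
#'
#' Joins a called preference table with a consensus table on their shared
#' key columns (any of `type`, `group`, `residue`, `chain`, `resname`,
#' `resno`, `part`) and summarises, per channel and overall, how many
#' called interactions are also hot spots, listing the disagreements.
#'
#' @param prefs a called `preference_table` (must have `call`).
#' @param consensus a `consensus_table` (or any data frame with `ratio`
#'   and/or `hot_spot`).
#' @return an object of class `hotspot_comparison`: list with `summary`
#'   (per-type and overall counts), `disagreements` (called but not hot),
#'   and `merged` (the joined table).
#' @export
compare_pharma_to_hotspots <- function(prefs, consensus) {
  if (!"call" %in% names(prefs)) {
    abort("`prefs` has no `call` column; run call_pharmacological() first")
  }
  if (!"hot_spot" %in% names(consensus)) {
    if (!"ratio" %in% names(consensus)) {
      abort("`consensus` needs a `hot_spot` or `ratio` column")
    }
    consensus <- dplyr::mutate(consensus, hot_spot = .data$ratio >= 0.5)
  }
  keys <- intersect(intersect(names(prefs), names(consensus)),
                    c("type", "group", "residue", "chain", "resname",
                      "resno", "part"))
  if (length(keys) == 0) abort("no shared key columns to join on")
  merged <- dplyr::left_join(tibble::as_tibble(prefs),
                             tibble::as_tibble(consensus), by = keys)
  called <- dplyr::filter(merged, .data$call)
  per_type <- called |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(n_called = dplyr::n(),
                     n_hotspot = sum(.data$hot_spot, na.rm = TRUE),
                     .groups = "drop")
  overall <- tibble::tibble(type = "all", n_called = nrow(called),
                            n_hotspot = sum(called$hot_spot, na.rm = TRUE))
  disagreements <- dplyr::filter(called, !.data$hot_spot | is.na(.data$hot_spot))
  structure(list(summary = dplyr::bind_rows(per_type, overall),
                 disagreements = disagreements, merged = merged),
            class = "hotspot_comparison")
}

#' @export
print.hotspot_comparison <- function(x, ...) {
  ov <- dplyr::filter(x$summary, .data$type == "all")
  cat("<hotspot_comparison> ", ov$n_called, " pharmacological interaction(s), ",
      ov$n_hotspot, " also hot spots\n", sep = "")
  if (nrow(x$disagreements) > 0) {
    keys <- intersect(names(x$disagreements), c("residue", "group"))
    lab <- x$disagreements[[keys[1]]]
    cat("  disagreements: ",
        paste(paste0(lab, "-", x$disagreements$type), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Write a preference or consensus table to TSV
#' @param x a tibble-like table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}
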