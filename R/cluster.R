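# Post-screening compound clustering: by interaction profile and by atomic
# composition.  The agglomerative linkage is implemented here (rather than
# delegated to stats::hclust) so that distance ties break by a fixed,
# input-order-invariant rule: merge the pair whose clusters have the
# lexicographically smallest (smallest member label, then largest member
# label).  With distinct distances the result is identical to hclust.

#' Atomic composition of a molecule
#'
#' Normalised heavy-atom counts over the element classes
#' `{C, N, O, S, P, halogen, other}` -- a cheap structural similarity
#' feature analogous to the amino-acid composition of a protein sequence.
#'
#' @param pose a `ligand_pose` with at least one heavy atom.
#' @return one-row tibble: `compound_id` + one fraction per element class.
#' @export
atomic_composition <- function(pose) {
  h <- heavy_atoms(pose$atoms)
  if (nrow(h) == 0) abort(paste0("no heavy atoms in ", pose$compound_id))
  classes <- c("C", "N", "O", "S", "P", "halogen", "other")
  counts <- table(factor(element_class(h$element), levels = classes))
  out <- tibble::as_tibble(setNames(as.list(as.numeric(counts) / nrow(h)),
                                    classes))
  dplyr::bind_cols(tibble::tibble(compound_id = pose$compound_id), out)
}

#' Atomic compositions of a pose list
#' @param poses list of `ligand_pose` objects (one row kept per compound).
#' @return tibble of composition vectors.
#' @export
atomic_compositions <- function(poses) {
  dplyr::distinct(dplyr::bind_rows(purrr::map(poses, atomic_composition)),
                  .data$compound_id, .keep_all = TRUE)
}

#' Distance between compounds in interaction-profile space
#'
#' Rows of the concatenated E|H|V binary profiles are compared with the
#' Euclidean metric (default) or the Jaccard distance for sparse profiles.
#'
#' @param profiles a single `interaction_profile` or a list of them sharing
#'   rows (they are concatenated column-wise).
#' @param method `"euclidean"` or `"jaccard"`.
#' @return a `dist` object labelled by compound id.
#' @export
profile_distance <- function(profiles, method = c("euclidean", "jaccard")) {
  method <- match.arg(method)
  m <- concat_profiles(profiles)
  if (method == "euclidean") return(stats::dist(m, method = "euclidean"))
  stats::dist(m, method = "binary")
}

concat_profiles <- function(profiles) {
  if (inherits(profiles, "interaction_profile")) profiles <- list(profiles)
  mats <- purrr::map(profiles, function(p) {
    colnames(p$matrix) <- paste0(p$type, ":", colnames(p$matrix))
    p$matrix
  })
  rows <- rownames(mats[[1]])
  for (m in mats[-1]) {
    if (!identical(rownames(m), rows)) abort("profiles have different rows")
  }
  do.call(cbind, mats)
}

#' Distance between compounds in atomic-composition space
#' @param compositions tibble from [atomic_compositions()].
#' @param method passed to [stats::dist()] (default Euclidean).
#' @return a `dist` object labelled by compound id.
#' @export
composition_distance <- function(compositions, method = "euclidean") {
  m <- as.matrix(compositions[, setdiff(names(compositions), "compound_id")])
  rownames(m) <- compositions$compound_id
  stats::dist(m, method = method)
}

#' Agglomerative hierarchical clustering with a deterministic tie-break
#'
#' Average linkage (UPGMA, the default), complete or single linkage over a
#' precomputed distance.  Equal-distance merge candidates are ordered by
#' the pair of smallest member labels, which makes the tree invariant to
#' the input order of the items.
#'
#' @param d a `dist` object (see [profile_distance()],
#'   [composition_distance()]) or a symmetric distance matrix.
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return an object of classes `compound_tree` and `hclust` (so
#'   [stats::cutree()], [ape::as.phylo()] etc. apply).
#' @export
hierarchical_cluster <- function(d, linkage = c("average", "complete",
                                                "single")) {
  linkage <- match.arg(linkage)
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 2) abort("need at least 2 items to cluster")
  labels <- rownames(dm) %||% as.character(seq_len(n))
  diag(dm) <- Inf

  # active clusters: id (hclust coding: -leaf or merge step), size,
  # smallest member label (for tie-breaks)
  active <- seq_len(n)
  code <- -seq_len(n)
  size <- rep(1L, n)
  min_label <- labels
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    idx <- which(active > 0)
    best <- NULL
    for (ai in seq_along(idx)) {
      i <- idx[ai]
      if (ai == length(idx)) break
      js <- idx[(ai + 1):length(idx)]
      dmin <- min(dm[i, js])
      for (j in js[dm[i, js] == dmin]) {
        key <- sort(c(min_label[i], min_label[j]))
        cand <- list(d = dmin, i = i, j = j, key = key)
        if (is.null(best) || cand$d < best$d ||
            (cand$d == best$d && (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- cand
        }
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort(c(code[i], code[j]))
    height[step] <- best$d

    others <- setdiff(idx, c(i, j))
    new_d <- switch(linkage,
      average = (size[i] * dm[i, others] + size[j] * dm[j, others]) /
        (size[i] + size[j]),
      complete = pmax(dm[i, others], dm[j, others]),
      single = pmin(dm[i, others], dm[j, others])
    )
    dm[i, others] <- new_d; dm[others, i] <- new_d
    dm[j, ] <- Inf; dm[, j] <- Inf
    active[j] <- 0L
    code[i] <- step
    size[i] <- size[i] + size[j]
    min_label[i] <- min(min_label[i], min_label[j])
  }

  tree <- structure(list(merge = merge, height = height,
                         order = hclust_order(merge, n),
                         labels = labels, method = linkage,
                         call = match.call(), dist.method = "euclidean"),
                    class = c("compound_tree", "hclust"))
  tree
}

hclust_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(n - 1)
}

#' Tidy a compound tree into its merge table
#' @param x a `compound_tree`.
#' @param ... ignored.
#' @return tibble with `step`, `left`, `right` (hclust coding) and
#'   `height`.
#' @method tidy compound_tree
#' @export
tidy.compound_tree <- function(x, ...) {
  tibble::tibble(step = seq_along(x$height), left = x$merge[, 1],
                 right = x$merge[, 2], height = x$height)
}

#' One-row summary of a compound tree
#' @param x a `compound_tree`.
#' @param ... ignored.
#' @return one-row tibble with leaf count, linkage and height range.
#' @method glance compound_tree
#' @export
glance.compound_tree <- function(x, ...) {
  tibble::tibble(n_leaves = length(x$labels), linkage = x$method,
                 min_height = min(x$height), max_height = max(x$height))
}

#' Cut a tree into flat clusters
#'
#' @param tree a `compound_tree`.
#' @param k number of clusters (1..n), or
#' @param h height threshold (merges above `h` are cut); give exactly one.
#' @return tibble with `compound_id` and `cluster`.
#' @export
cut_tree <- function(tree, k = NULL, h = NULL) {
  if (is.null(k) == is.null(h)) abort("give exactly one of `k` or `h`")
  n <- length(tree$labels)
  if (!is.null(k) && (k < 1 || k > n)) {
    abort(paste0("k must be in 1..", n))
  }
  cl <- stats::cutree(tree, k = k, h = h)
  tibble::tibble(compound_id = tree$labels, cluster = unname(cl))
}

#' Pick one representative compound per cluster
#'
#' The representative is the member with the best (lowest) combined
#' pharmacological score, supporting diversity-preserving hit selection.
#'
#' @param clusters tibble from [cut_tree()].
#' @param scores a `pharma_scores` tibble.
#' @return `clusters` joined with scores plus an `is_representative`
#'   column.
#' @export
select_representatives <- function(clusters, scores) {
  merged <- dplyr::left_join(clusters,
                             tibble::as_tibble(scores)[, c("compound_id",
                                                           "combined")],
                             by = "compound_id")
  merged |>
    dplyr::group_by(.data$cluster) |>
    dplyr::mutate(is_representative =
                    dplyr::row_number(dplyr::pick("combined", "compound_id")) == 1L) |>
    dplyr::ungroup()
}

#' Export a dendrogram for tree-viewer software
#'
#' `newick` writes a Newick string with branch lengths derived from merge
#' heights (leaf labels containing whitespace or Newick metacharacters are
#' single-quoted).  `cdt_gtr` writes the Eisen clustered-data-table pair:
#' a `.cdt` with one row per leaf in dendrogram order plus a `.gtr`
#' describing the n-1 merges (correlation column = 1 - height/max height).
#'
#' @param tree a `compound_tree`.
#' @param path output path; for `cdt_gtr` the extension is replaced by
#'   `.cdt`/`.gtr`.
#' @param format `"newick"` or `"cdt_gtr"`.
#' @param data optional numeric matrix (rows = leaves) written as the CDT
#'   data block; defaults to zeros with a single placeholder column.
#' @return the path(s) written, invisibly.
#' @export
export_dendrogram <- function(tree, path, format = c("newick", "cdt_gtr"),
                              data = NULL) {
  format <- match.arg(format)
  if (format == "newick") {
    writeLines(paste0(newick_string(tree), ";"), path)
    return(invisible(path))
  }
  base <- sub("\\.(cdt|gtr|txt|tsv)$", "", path)
  paths <- paste0(base, c(".cdt", ".gtr"))
  n <- length(tree$labels)
  max_h <- max(tree$height)
  corr <- if (max_h > 0) 1 - tree$height / max_h else rep(1, n - 1)
  node_name <- function(code) {
    if (code < 0) paste0("GENE", -code, "X") else paste0("NODE", code, "X")
  }
  gtr <- tibble::tibble(
    NODEID = paste0("NODE", seq_len(n - 1), "X"),
    LEFT = vapply(tree$merge[, 1], node_name, character(1)),
    RIGHT = vapply(tree$merge[, 2], node_name, character(1)),
    CORRELATION = corr
  )
  readr::write_tsv(gtr, paths[2], col_names = FALSE)

  if (is.null(data)) {
    data <- matrix(0, nrow = n, ncol = 1,
                   dimnames = list(tree$labels, "VALUE"))
  }
  data <- data[tree$labels, , drop = FALSE]
  ord <- tree$order
  cdt_head <- paste(c("GID", "NAME", "GWEIGHT", colnames(data)),
                    collapse = "\t")
  cdt_rows <- vapply(ord, function(i) {
    paste(c(paste0("GENE", i, "X"), tree$labels[i], "1",
            format(data[i, ], trim = TRUE)), collapse = "\t")
  }, character(1))
  writeLines(c(cdt_head, cdt_rows), paths[1])
  invisible(paths)
}

newick_string <- function(tree) {
  quote_label <- function(x) {
    if (grepl("[^A-Za-z0-9_.|-]", x)) {
      paste0("'", gsub("'", "''", x), "'")
    } else x
  }
  node_height <- function(code) if (code < 0) 0 else tree$height[code]
  recurse <- function(code) {
    if (code < 0) return(quote_label(tree$labels[-code]))
    h <- tree$height[code]
    kids <- vapply(tree$merge[code, ], function(child) {
      paste0(recurse(child), ":",
             format(h - node_height(child), digits = 10))
    }, character(1))
    paste0("(", paste(kids, collapse = ","), ")")
  }
  recurse(length(tree$height))
}
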