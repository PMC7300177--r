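#' Assemble the subjects x waveform-points matrix
#'
#' Stacks each subject's 10 x 101 waveform set into one row of
#' 10 x 101 = 1010 columns (channels in canonical order, each spanning
#' 0-100% of stance) and standardizes every column to mean 0 / SD 1.
#' The column means and SDs are retained so reconstructions can be
#' mapped back to original units.
#'
#' @param sets Named list of [waveform_set()] objects (all subjects).
#' @param sd_floor Optional positive floor applied to column SDs; by
#'   default (`NULL`) a zero-variance column is an error.
#' @return A `waveform_matrix`: list with standardized `values`
#'   (n x 1010), `center`, `scale`, `row_ids`, `col_channel`,
#'   `col_percent`.
#' @export
assemble_matrix <- function(sets, sd_floor = NULL) {
  channels <- waveform_channels()
  rows <- lapply(sets, function(ws) {
    stopifnot(inherits(ws, "waveform_set"))
    missing <- setdiff(channels, rownames(ws$waveforms))
    if (length(missing))
      stop("subject ", ws$subject_id, " is missing channel(s): ",
           paste(missing, collapse = ", "))
    as.vector(t(ws$waveforms[channels, ]))
  })
  ids <- vapply(sets, function(ws) as.character(ws$subject_id), character(1))
  if (anyDuplicated(ids)) stop("duplicated subject id: ", ids[duplicated(ids)][1])
  x <- do.call(rbind, rows)
  rownames(x) <- ids
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl == 0)) {
    if (is.null(sd_floor))
      stop("zero-variance waveform column(s) at position(s): ",
           paste(utils::head(which(scl == 0), 5), collapse = ", "),
           "; set sd_floor to standardize them with an epsilon SD")
    scl <- pmax(scl, sd_floor)
  }
  values <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  structure(list(values = values, center = ctr, scale = scl,
                 row_ids = ids,
                 col_channel = rep(channels, each = 101),
                 col_percent = rep(0:100, times = length(channels))),
            class = "waveform_matrix")
}

#' Principal component analysis of the waveform matrix
#'
#' Singular value decomposition of the standardized matrix
#' (covariance-free PCA). With n generic subject rows the centered
#' matrix has rank n - 1, so exactly n - 1 components carry nonzero
#' variance; components are ordered by decreasing variance and the sign
#' of each is fixed so that its largest-magnitude loading is positive.
#'
#' @param wm A `waveform_matrix` from [assemble_matrix()].
#' @param tol Variance tolerance below which a component is considered
#'   null and dropped (relative to the leading component).
#' @return A `waveform_pca`: list with `components` (k x 1010 loadings),
#'   `scores` (n x k), `explained_variance_ratio` (length k),
#'   `n_components`, plus the originating matrix metadata.
#' @export
fit_waveform_pca <- function(wm, tol = 1e-10) {
  stopifnot(inherits(wm, "waveform_matrix"))
  n <- nrow(wm$values)
  if (n < 3) stop("PCA needs at least 3 subjects")
  pc <- stats::prcomp(wm$values, center = FALSE, scale. = FALSE)
  vars <- pc$sdev^2
  keep <- which(vars > tol * vars[1])
  keep <- keep[keep <= min(n - 1, ncol(wm$values))]
  rot <- pc$rotation[, keep, drop = FALSE]
  sco <- pc$x[, keep, drop = FALSE]
  # sign convention: largest-magnitude loading of each component positive
  for (j in seq_along(keep)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) { rot[, j] <- -rot[, j]; sco[, j] <- -sco[, j] }
  }
  colnames(rot) <- colnames(sco) <- paste0("PC", seq_along(keep))
  structure(list(components = t(rot), scores = sco,
                 explained_variance_ratio = vars[keep] / sum(vars),
                 n_components = length(keep),
                 center = wm$center, scale = wm$scale,
                 col_channel = wm$col_channel, col_percent = wm$col_percent,
                 row_ids = wm$row_ids),
            class = "waveform_pca")
}

#' Per-channel variance attribution of one principal component
#'
#' Squared correlation (r^2) between the component's score vector and
#' each of the 1010 standardized waveform columns, summed within each
#' of the 10 channels and reported as relative proportions summing to
#' 100%. Used to name the joints/planes a component loads on.
#'
#' @param pca A `waveform_pca`.
#' @param wm The `waveform_matrix` it was fitted on.
#' @param component_index Component number (1-based).
#' @return Named numeric vector of 10 percentages summing to 100.
#' @export
variance_attribution <- function(pca, wm, component_index) {
  stopifnot(inherits(pca, "waveform_pca"), inherits(wm, "waveform_matrix"))
  if (component_index < 1 || component_index > pca$n_components)
    stop("component index out of range (1..", pca$n_components, ")")
  sc <- pca$scores[, component_index]
  r2 <- as.vector(stats::cor(sc, wm$values))^2
  sums <- tapply(r2, factor(wm$col_channel, levels = waveform_channels()), sum)
  100 * sums / sum(sums)
}

#' Build the candidate feature set for classification
#'
#' Combines each subject's PC scores with the nine discrete GRF
#' variables (standardized to mean 0 / SD 1 across subjects, matching
#' the waveform treatment) and the experience class labels. Features
#' are ordered PCs first, then GRF variables, giving
#' `n_components + 9` candidates (86 for a 78-subject cohort).
#'
#' @param pca A `waveform_pca`.
#' @param grf Data frame from [grf_table()] (`subject_id` + 9 columns).
#' @param labels Factor (or character) of class labels, named by
#'   subject id or ordered like `pca$row_ids`.
#' @return A `candidate_set`: list with `features` (n x k matrix),
#'   `labels`, `feature_names`, `pc_names`, `grf_names`, `subject_ids`.
#' @export
build_candidates <- function(pca, grf, labels) {
  stopifnot(inherits(pca, "waveform_pca"))
  ids <- pca$row_ids
  if (anyDuplicated(grf$subject_id))
    stop("duplicated subject id in GRF table: ",
         grf$subject_id[duplicated(grf$subject_id)][1])
  if (!setequal(grf$subject_id, ids)) {
    diff1 <- setdiff(ids, grf$subject_id); diff2 <- setdiff(grf$subject_id, ids)
    stop("subject mismatch between PCA and GRF table; missing from GRF: [",
         paste(diff1, collapse = ", "), "], extra in GRF: [",
         paste(diff2, collapse = ", "), "]")
  }
  gm <- as.matrix(grf[match(ids, grf$subject_id), grf_variable_names()])
  rownames(gm) <- ids
  gsd <- apply(gm, 2, stats::sd)
  if (any(gsd == 0)) stop("zero-variance GRF variable: ",
                          grf_variable_names()[which(gsd == 0)[1]])
  gm <- scale(gm)
  if (!is.null(names(labels))) labels <- labels[ids]
  labels <- factor(as.character(labels), levels = experience_levels())
  if (length(labels) != length(ids) || anyNA(labels))
    stop("labels must cover every subject with a valid experience level")
  features <- cbind(pca$scores, gm)
  structure(list(features = features, labels = labels,
                 feature_names = colnames(features),
                 pc_names = colnames(pca$scores),
                 grf_names = grf_variable_names(),
                 subject_ids = ids),
            class = "candidate_set")
}

#' Write the candidate feature table to CSV
#' @param candidates A `candidate_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  df <- data.frame(subject_id = candidates$subject_ids,
                   candidates$features,
                   label = candidates$labels, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
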