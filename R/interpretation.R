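#' Reconstruct waveforms from a subset of principal components
#'
#' Restricts the score matrix to the selected components, multiplies
#' back through the loadings, and un-standardizes with the stored
#' column means and SDs, yielding waveforms in original units. An empty
#' selection reconstructs every subject to the column means.
#'
#' @param pca A `waveform_pca`.
#' @param selected_pcs Character vector of component names ("PC2", ...)
#'   or integer indices; may be empty.
#' @return Numeric matrix (subjects x 1010) in original units.
#' @export
reconstruct_waveforms <- function(pca, selected_pcs) {
  stopifnot(inherits(pca, "waveform_pca"))
  sel <- resolve_pcs(pca, selected_pcs)
  std <- if (length(sel) == 0)
    matrix(0, nrow = nrow(pca$scores), ncol = ncol(pca$components))
  else
    pca$scores[, sel, drop = FALSE] %*% pca$components[sel, , drop = FALSE]
  out <- sweep(sweep(std, 2, pca$scale, "*"), 2, pca$center, "+")
  rownames(out) <- pca$row_ids
  out
}

resolve_pcs <- function(pca, selected_pcs) {
  if (length(selected_pcs) == 0) return(integer())
  if (is.character(selected_pcs)) {
    # ignore non-PC features (e.g. GRF names from a model's selection)
    selected_pcs <- selected_pcs[grepl("^PC[0-9]+$", selected_pcs)]
    sel <- match(selected_pcs, rownames(pca$components))
    if (anyNA(sel)) stop("unknown component: ",
                         selected_pcs[which(is.na(sel))[1]])
  } else {
    sel <- as.integer(selected_pcs)
    if (any(sel < 1 | sel > pca$n_components))
      stop("component index out of range (1..", pca$n_components, ")")
  }
  sel
}

#' Pointwise effect-size profile of one channel
#'
#' Cohen's d between the positive class and the remaining subjects at
#' each of the 101 stance points of a channel, with the maximal runs
#' where `|d|` meets the threshold flagged as regions of (at least)
#' medium effect.
#'
#' @param waveforms Subjects x 1010 matrix (reconstructed via
#'   [reconstruct_waveforms()], or the original data mapped back to
#'   original units).
#' @param labels Experience labels, one per subject row.
#' @param positive_class Class compared against the rest.
#' @param channel One of [waveform_channels()].
#' @param threshold Effect-size threshold; 0.5 is the conventional
#'   medium effect (default).
#' @param pca A `waveform_pca` (used for the column layout).
#' @return An `effect_profile`: list with `channel`, `d` (101 values),
#'   `flagged_regions` (data frame `start_pct`, `end_pct`), `threshold`.
#' @export
effect_profile <- function(waveforms, labels, positive_class, channel,
                           threshold = 0.5, pca) {
  stopifnot(channel %in% waveform_channels())
  pos <- labels == positive_class
  if (sum(pos) < 2 || sum(!pos) < 2)
    stop("need at least 2 subjects on each side of the comparison")
  cols <- which(pca$col_channel == channel)
  d <- vapply(cols, function(j) cohens_d(waveforms[pos, j], waveforms[!pos, j]),
              numeric(1))
  over <- abs(d) >= threshold
  r <- rle(over)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  flagged <- data.frame(start_pct = starts[r$values] - 1,
                        end_pct = ends[r$values] - 1)
  structure(list(channel = channel, d = d, flagged_regions = flagged,
                 threshold = threshold),
            class = "effect_profile")
}

#' Interpretation summary of one classification model
#'
#' Splits the model's selected features into principal components and
#' discrete GRF variables, totals the explained variance of the
#' selected components, attributes the top selected component to
#' channels, and computes the per-channel effect-size profiles (with
#' flagged medium-effect regions) on the waveforms reconstructed from
#' the selected components.
#'
#' @param report A `one_vs_all_report`.
#' @param pca The `waveform_pca` the candidates were built from.
#' @param wm The originating `waveform_matrix`.
#' @param labels Experience labels per subject.
#' @param threshold Effect-size threshold for region flagging.
#' @param on_reconstructed Compute profiles on the PC-reconstruction
#'   (default, matching the interpretation procedure) or on the
#'   original waveforms.
#' @return A `model_summary`: list with `positive_class`,
#'   `selected_pcs`, `selected_grf`, `explained_variance_selected`,
#'   `top_pc`, `top_pc_attribution`, `profiles` (per channel).
#' @export
summarize_model <- function(report, pca, wm, labels, threshold = 0.5,
                            on_reconstructed = TRUE) {
  stopifnot(inherits(report, "one_vs_all_report"))
  if (!identical(pca$row_ids, wm$row_ids))
    stop("PCA and waveform matrix describe different subject sets")
  sel <- report$selected_features
  sel_pcs <- sel[grepl("^PC[0-9]+$", sel)]
  sel_grf <- setdiff(sel, sel_pcs)
  idx <- resolve_pcs(pca, sel_pcs)
  evr <- sum(pca$explained_variance_ratio[idx])
  top_pc <- if (length(idx)) sel_pcs[which.max(pca$explained_variance_ratio[idx])]
            else NA_character_
  waves <- if (on_reconstructed) reconstruct_waveforms(pca, sel_pcs)
           else sweep(sweep(wm$values, 2, wm$scale, "*"), 2, wm$center, "+")
  profiles <- lapply(waveform_channels(), function(ch)
    effect_profile(waves, labels, report$positive_class, ch, threshold, pca))
  names(profiles) <- waveform_channels()
  structure(list(positive_class = report$positive_class,
                 selected_pcs = sel_pcs, selected_grf = sel_grf,
                 explained_variance_selected = evr,
                 top_pc = top_pc,
                 top_pc_attribution = if (length(idx))
                   variance_attribution(pca, wm, resolve_pcs(pca, top_pc)) else NULL,
                 profiles = profiles),
            class = "model_summary")
}

#' @export
print.model_summary <- function(x, ...) {
  cat(sprintf("Interpretation: %s vs all\n", x$positive_class))
  cat(sprintf("  %d PCs (%.1f%% variance) + %d GRF features selected\n",
              length(x$selected_pcs), 100 * x$explained_variance_selected,
              length(x$selected_grf)))
  if (!is.na(x$top_pc)) {
    att <- sort(x$top_pc_attribution, decreasing = TRUE)
    cat(sprintf("  top component %s loads on: %s (%.1f%%), %s (%.1f%%)\n",
                x$top_pc, names(att)[1], att[1], names(att)[2], att[2]))
  }
  flagged <- vapply(x$profiles, function(p) nrow(p$flagged_regions) > 0, logical(1))
  cat("  channels with medium-effect regions:",
      paste(names(flagged)[flagged], collapse = ", "), "\n")
  invisible(x)
}

#' Write interpretation outputs
#'
#' `interpretation.json` plus one CSV effect profile per channel.
#' @param summaries Named list of `model_summary` objects.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_interpretation <- function(summaries, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- lapply(summaries, function(s) {
    list(positive_class = s$positive_class,
         selected_pcs = s$selected_pcs,
         selected_grf = s$selected_grf,
         explained_variance_selected = s$explained_variance_selected,
         top_pc = s$top_pc,
         top_pc_attribution = as.list(s$top_pc_attribution),
         flagged_regions = lapply(s$profiles, function(p) p$flagged_regions))
  })
  jsonlite::write_json(out, file.path(dir, "interpretation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(summaries)) {
    prof <- do.call(rbind, lapply(summaries[[nm]]$profiles, function(p)
      data.frame(channel = p$channel, stance_pct = 0:100, d = p$d)))
    utils::write.csv(prof, file.path(dir, paste0("effect_profile_", nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Plot group-mean reconstructed waveforms with flagged regions
#'
#' Convenience ggplot of one channel's group means over stance with the
#' medium-effect regions of a model shaded. Requires ggplot2.
#'
#' @param waveforms Subjects x 1010 matrix in original units.
#' @param labels Experience labels per subject.
#' @param channel Channel to plot.
#' @param profile Optional `effect_profile` whose regions to shade.
#' @param pca A `waveform_pca` (column layout).
#' @return A ggplot object.
#' @export
plot_channel_means <- function(waveforms, labels, channel, profile = NULL, pca) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  cols <- which(pca$col_channel == channel)
  df <- do.call(rbind, lapply(levels(factor(labels)), function(g)
    data.frame(group = g, stance_pct = 0:100,
               value = colMeans(waveforms[labels == g, cols, drop = FALSE]))))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$stance_pct, y = .data$value,
                                        colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "stance (%)", y = channel)
  if (!is.null(profile) && nrow(profile$flagged_regions))
    p <- p + ggplot2::annotate("rect",
                               xmin = profile$flagged_regions$start_pct,
                               xmax = profile$flagged_regions$end_pct,
                               ymin = -Inf, ymax = Inf, alpha = 0.15)
  p
}
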