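# DHFR-PCA plate scoring: plate-background normalization, PCA scores,
# quantile-based interaction calling, SH3-dependency classification, and
# stress-condition growth scores.
#
# A plate grid is a long-form data frame with one row per array position:
#   plate_id, row, col, is_border, log2_size, qc_pass, and either
#   bait/prey labels (interaction screens) or a strain label (growth
#   assays); optional condition and timepoint columns.

plate_cols_screen <- c("plate_id", "row", "col", "bait", "prey",
                       "is_border", "log2_size", "qc_pass")

check_plate <- function(grid, cols = plate_cols_screen) {
  missing <- setdiff(cols, names(grid))
  if (length(missing) > 0L) {
    stop("plate grid lacks column(s): ", paste(missing, collapse = ", "))
  }
  invisible(grid)
}

#' Normalize a plate to its background level
#'
#' Subtracts the plate background from every colony's log2 size so scores
#' are comparable across plates. The background is the median of qc-passing
#' non-border values; plates with no detectable background (e.g. a bait that
#' grows nowhere) can instead be assigned the measured background of a
#' matched reference plate via \code{background_override}.
#'
#' @param grid Plate grid (log2-transformed colony sizes).
#' @param background_override Optional externally measured background.
#' @return The grid with \code{log2_size} background-subtracted; the
#'   background used is attached as attribute \code{"background"}.
#' @export
normalize_plate <- function(grid, background_override = NULL) {
  check_plate(grid, c("row", "col", "is_border", "log2_size", "qc_pass"))
  if (is.null(background_override)) {
    vals <- grid$log2_size[grid$qc_pass & !grid$is_border]
    vals <- vals[is.finite(vals)]
    if (length(vals) == 0L) {
      stop("no qc-passing non-border colonies and no background override")
    }
    background <- stats::median(vals)
  } else {
    background <- background_override
  }
  grid$log2_size <- grid$log2_size - background
  attr(grid, "background") <- background
  grid
}

#' Collect PCA scores per bait-prey pair
#'
#' Pools normalized replicate values across plates, removes replicates whose
#' colony failed the diploid-selection step, drops border control pairs, and
#' keeps pairs with at least \code{min_replicates} surviving replicates.
#' The PCA score of a pair is the median of its replicate values.
#'
#' @param grids One normalized plate grid or a list of them (rows are
#'   concatenated).
#' @param diploid_grids Optional diploid-selection grids aligned by
#'   (plate_id, row, col); replicates whose diploid colony has
#'   \code{qc_pass = FALSE} are removed.
#' @param min_replicates Minimum surviving replicates per pair (default 2).
#' @return Data frame with \code{bait}, \code{prey}, \code{pca_score},
#'   \code{n_replicates} and a list column \code{replicate_values}.
#' @export
collect_ppi_scores <- function(grids, diploid_grids = NULL,
                               min_replicates = 2L) {
  if (is.data.frame(grids)) grids <- list(grids)
  grid <- do.call(rbind, lapply(grids, check_plate))
  if (!is.null(diploid_grids)) {
    if (is.data.frame(diploid_grids)) diploid_grids <- list(diploid_grids)
    dip <- do.call(rbind, diploid_grids)
    check_plate(dip, c("plate_id", "row", "col", "qc_pass"))
    key <- function(d) paste(d$plate_id, d$row, d$col, sep = "\r")
    m <- match(key(grid), key(dip))
    if (anyNA(m)) stop("screen and diploid grids misaligned by position")
    grid <- grid[dip$qc_pass[m], , drop = FALSE]
  }
  grid <- grid[grid$qc_pass & !grid$is_border & is.finite(grid$log2_size), ,
               drop = FALSE]
  if (nrow(grid) == 0L) stop("no scoreable colonies")
  pair <- interaction(grid$bait, grid$prey, drop = TRUE, sep = "\r")
  vals <- split(grid$log2_size, pair)
  keep <- lengths(vals) >= min_replicates
  vals <- vals[keep]
  labels <- do.call(rbind, strsplit(names(vals), "\r", fixed = TRUE))
  out <- data.frame(bait = labels[, 1L], prey = labels[, 2L],
                    pca_score = vapply(vals, stats::median, numeric(1L)),
                    n_replicates = lengths(vals),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$replicate_values <- unname(vals)
  out <- out[order(out$bait, out$prey), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call interactions from the top of the PCA score distribution
#'
#' Declares a pair an interaction when its PCA score is at or above the
#' (1 - top_quantile) quantile of the pooled score distribution (linear
#' interpolation; ties at the threshold are included). The screen-wide
#' defaults in the source experiments are 0.073 (first screen) and 0.0275
#' (Sla1 shuffling screen).
#'
#' @param scores Output of [collect_ppi_scores()].
#' @param top_quantile Fraction of the score distribution called positive.
#' @return Data frame of called \code{bait}/\code{prey} pairs with their
#'   scores; the threshold is attached as attribute \code{"threshold"}.
#' @export
detect_interactions <- function(scores, top_quantile = 0.073) {
  stopifnot(top_quantile > 0, top_quantile < 1)
  if (nrow(scores) == 0L) stop("empty score list")
  threshold <- stats::quantile(scores$pca_score, 1 - top_quantile,
                               names = FALSE)
  out <- scores[scores$pca_score >= threshold,
                c("bait", "prey", "pca_score"), drop = FALSE]
  attr(out, "threshold") <- threshold
  out
}

#' PCA score ratio of a mutant over a wild-type screen
#'
#' Scores are already log2, so the ratio of colony sizes is the difference
#' mutant score minus wild-type score.
#'
#' @param mut,wt PCA scores (numeric) of the same pair in the SH3-deleted
#'   and wild-type screens.
#' @return Log2 score ratio.
#' @export
score_ratio <- function(mut, wt) {
  stopifnot(is.numeric(mut), is.numeric(wt))
  mut - wt
}

#' Classify bait-prey pairs by SH3 dependency
#'
#' Decision table over detection status in the wild-type and SH3-deleted
#' screens and the score ratio of pairs detected in both:
#' \itemize{
#'   \item detected in WT only: \code{dependent_lost}
#'   \item detected in both, ratio at or below the lower ratio quantile:
#'     \code{dependent_weaker}
#'   \item detected in both, ratio between the quantiles:
#'     \code{independent}
#'   \item detected in both, ratio at or above the upper quantile:
#'     \code{inhibited_stronger}
#'   \item detected in mutant only: \code{inhibited_gained}
#' }
#' Ratio quantiles are computed on the pooled ratio distribution of pairs
#' detected in both screens; threshold ties are classified into the extreme
#' class. Pairs detected in neither screen are skipped with a message.
#'
#' @param wt_calls,mut_calls Data frames of detected pairs
#'   (\code{bait}, \code{prey}), as from [detect_interactions()].
#' @param ratios Data frame \code{bait}, \code{prey}, \code{ratio} for pairs
#'   scored in both screens.
#' @param ratio_quantile Tail fraction defining weaker/stronger calls
#'   (same convention as the screen's detection threshold, e.g. 0.073).
#' @return Data frame with \code{bait}, \code{prey}, \code{wt_detected},
#'   \code{mut_detected}, \code{score_ratio} and \code{class}.
#' @export
classify_ppis <- function(wt_calls, mut_calls, ratios,
                          ratio_quantile = 0.073) {
  stopifnot(ratio_quantile > 0, ratio_quantile < 0.5)
  pkey <- function(d) paste(d$bait, d$prey, sep = "\r")
  wt_k <- pkey(wt_calls)
  mut_k <- pkey(mut_calls)
  universe <- unique(c(wt_k, mut_k))
  skipped <- setdiff(pkey(ratios), universe)
  if (length(skipped) > 0L) {
    message(length(skipped), " pair(s) detected in neither screen; skipped")
  }
  ratio_k <- pkey(ratios)
  both <- intersect(wt_k, mut_k)
  r_both <- ratios$ratio[match(both, ratio_k)]
  if (length(both) > 0L && anyNA(r_both)) {
    stop("missing ratio for pair(s) detected in both screens")
  }
  lo <- stats::quantile(r_both, ratio_quantile, names = FALSE)
  hi <- stats::quantile(r_both, 1 - ratio_quantile, names = FALSE)
  labels <- do.call(rbind, strsplit(universe, "\r", fixed = TRUE))
  out <- data.frame(bait = labels[, 1L], prey = labels[, 2L],
                    wt_detected = universe %in% wt_k,
                    mut_detected = universe %in% mut_k,
                    score_ratio = ratios$ratio[match(universe, ratio_k)],
                    stringsAsFactors = FALSE)
  out$class <- ifelse(out$wt_detected & !out$mut_detected, "dependent_lost",
               ifelse(!out$wt_detected & out$mut_detected, "inhibited_gained",
               ifelse(out$score_ratio <= lo, "dependent_weaker",
               ifelse(out$score_ratio >= hi, "inhibited_stronger",
                      "independent"))))
  attr(out, "ratio_thresholds") <- c(lower = lo, upper = hi)
  out
}

#' Growth scores under a stress condition
#'
#' For each condition, exactly two plate replicates are required. Plate
#' effects are removed by aligning each plate's median (over qc-passing
#' non-border colonies) to the mean of the two plate medians; strain medians
#' are then computed per plate, strains whose medians differ by more than
#' \code{discordance_cutoff} log2 units between the two plates are removed
#' as discordant, and the growth score is the mean of the two per-plate
#' medians.
#'
#' @param plates Plate grid(s) with a \code{strain} column and optional
#'   \code{condition}/\code{timepoint} columns (log2 colony sizes).
#' @param timepoint_h Acquisition timepoint used for scoring (default 74 h);
#'   applied only when a \code{timepoint} column is present.
#' @param discordance_cutoff Maximum allowed inter-plate difference of
#'   strain medians (default 2 log2 units).
#' @return Data frame with \code{strain}, \code{condition},
#'   \code{median_plate1}, \code{median_plate2}, \code{growth_score};
#'   discordant strains are reported in attribute \code{"discordant"}.
#' @export
growth_scores <- function(plates, timepoint_h = 74,
                          discordance_cutoff = 2.0) {
  if (is.data.frame(plates)) plates <- list(plates)
  grid <- do.call(rbind, plates)
  check_plate(grid, c("plate_id", "strain", "is_border", "log2_size",
                      "qc_pass"))
  if ("timepoint" %in% names(grid)) {
    grid <- grid[grid$timepoint == timepoint_h, , drop = FALSE]
  }
  if (!"condition" %in% names(grid)) grid$condition <- "none"
  res <- lapply(split(grid, grid$condition), function(g) {
    plate_ids <- sort(unique(g$plate_id))
    if (length(plate_ids) != 2L) {
      stop("condition '", g$condition[1L], "' has ", length(plate_ids),
           " plate replicates; exactly 2 required")
    }
    g <- g[g$qc_pass & !g$is_border, , drop = FALSE]
    pm <- vapply(plate_ids, function(p) {
      stats::median(g$log2_size[g$plate_id == p])
    }, numeric(1L))
    # plate-effect correction: align each plate to the common median level
    g$log2_size <- g$log2_size + (mean(pm) - pm[match(g$plate_id, plate_ids)])
    med <- tapply(g$log2_size, list(g$strain, g$plate_id), stats::median)
    med <- med[, as.character(plate_ids), drop = FALSE]
    if (anyNA(med)) stop("strain missing from one plate replicate")
    disc <- abs(med[, 1L] - med[, 2L]) > discordance_cutoff
    out <- data.frame(strain = rownames(med), condition = g$condition[1L],
                      median_plate1 = med[, 1L], median_plate2 = med[, 2L],
                      growth_score = rowMeans(med),
                      stringsAsFactors = FALSE, row.names = NULL)
    list(scores = out[!disc, , drop = FALSE],
         discordant = rownames(med)[disc])
  })
  out <- do.call(rbind, c(lapply(res, `[[`, "scores"),
                          list(make.row.names = FALSE)))
  attr(out, "discordant") <- unlist(lapply(res, `[[`, "discordant"),
                                    use.names = FALSE)
  out
}

#' Read / write plate grids as long-form TSV
#'
#' @param path File path.
#' @return \code{read_plate_tsv}: a plate grid data frame.
#' @export
read_plate_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @param grid Plate grid (or any long-form table).
#' @rdname read_plate_tsv
#' @export
write_plate_tsv <- function(grid, path) {
  utils::write.table(grid, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
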