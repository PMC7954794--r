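# Deep mutational scanning scores from variant count tables.
#
# Count tables are long-form data frames with columns: condition
# ("reference" or "selection"), replicate, position (1-based), codon,
# count, depth, wt_codon. Scores are selection/reference frequency log2
# ratios (with a count-level pseudocount) scaled by the median ratio of
# synonymous codon substitutions.

check_counts <- function(tab) {
  need <- c("condition", "replicate", "position", "codon", "count",
            "depth", "wt_codon")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) {
    stop("count table lacks column(s): ", paste(missing, collapse = ", "))
  }
  invisible(tab)
}

#' Pseudocounted variant frequencies
#'
#' frequency = (count + pseudocount) / depth, per variant. The pseudocount
#' is applied at the count level (the default 0.5 keeps zero-count variants
#' finite on the log scale without swamping observed frequencies).
#'
#' @param tab Variant count table (one condition/replicate).
#' @param pseudocount Count-level pseudocount (default 0.5). Set to 0 for
#'   plain count/depth frequencies.
#' @return The table with a \code{freq} column; zero-depth positions are
#'   dropped with a warning.
#' @export
variant_frequencies <- function(tab, pseudocount = 0.5) {
  check_counts(tab)
  zero <- tab$depth <= 0
  if (any(zero)) {
    warning("skipping ", length(unique(tab$position[zero])),
            " position(s) with zero depth")
    tab <- tab[!zero, , drop = FALSE]
  }
  tab$freq <- (tab$count + pseudocount) / tab$depth
  tab
}

#' Selection-over-reference log2 frequency ratios
#'
#' ratio = log2(selection frequency / reference frequency), matched by
#' (position, codon). A variant absent from one condition is treated as
#' count 0 at that position's depth there.
#'
#' @param sel,ref Frequency tables (see [variant_frequencies()]) for the
#'   selection and reference condition of one replicate.
#' @param pseudocount Pseudocount used to impute frequencies for variants
#'   missing from one condition.
#' @return Data frame with \code{position}, \code{codon}, \code{wt_codon},
#'   \code{replicate} and \code{ratio}.
#' @export
variant_log_ratios <- function(sel, ref, pseudocount = 0.5) {
  key <- function(d) paste(d$position, d$codon, sep = "\r")
  ks <- key(sel)
  kr <- key(ref)
  all_k <- union(ks, kr)
  pos_depth <- function(d) {
    dd <- unique(d[, c("position", "depth")])
    stats::setNames(dd$depth, dd$position)
  }
  impute <- function(d, kk, depths) {
    m <- match(all_k, kk)
    f <- d$freq[m]
    pos <- as.integer(sub("\r.*", "", all_k))
    f[is.na(m)] <- pseudocount / depths[as.character(pos[is.na(m)])]
    f
  }
  f_sel <- impute(sel, ks, pos_depth(sel))
  f_ref <- impute(ref, kr, pos_depth(ref))
  if (anyNA(f_sel) || anyNA(f_ref)) {
    stop("variant at a position absent from one condition entirely")
  }
  src <- ifelse(all_k %in% ks, match(all_k, ks), NA)
  wt <- ifelse(is.na(src), ref$wt_codon[match(all_k, kr)], sel$wt_codon[src])
  data.frame(position = as.integer(sub("\r.*", "", all_k)),
             codon = sub(".*\r", "", all_k),
             wt_codon = wt,
             replicate = sel$replicate[1L],
             ratio = log2(f_sel / f_ref),
             stringsAsFactors = FALSE)
}

# flag synonymous variants: same encoded aa as the WT codon, different codon
annotate_variants <- function(ratios) {
  ratios$aa <- codon_to_aa(ratios$codon)
  ratios$wt_aa <- codon_to_aa(ratios$wt_codon)
  ratios$is_wt <- ratios$codon == ratios$wt_codon
  ratios$is_synonymous <- !ratios$is_wt & ratios$aa == ratios$wt_aa
  ratios
}

#' DMS scores scaled by the synonymous-variant median
#'
#' Each replicate's ratios are scaled by subtracting that replicate's median
#' synonymous ratio (synonymous codon substitutions serve as the neutral
#' reference), replicates are then averaged per variant, and the averaged
#' scores are re-centered on the pooled synonymous median so that the median
#' synonymous DMS score is exactly 0 by construction.
#'
#' @param ratios Ratio table(s) from [variant_log_ratios()] — one data frame
#'   or a list with one element per biological replicate.
#' @return Data frame of variant scores: \code{position}, \code{codon},
#'   \code{aa}, \code{wt_aa}, \code{is_synonymous}, \code{ratio} (replicate
#'   mean of unscaled ratios), \code{dms_score}, \code{n_replicates}.
#' @export
dms_scores <- function(ratios) {
  if (is.data.frame(ratios)) ratios <- list(ratios)
  scaled <- lapply(ratios, function(r) {
    r <- annotate_variants(r)
    syn <- r$ratio[r$is_synonymous]
    if (length(syn) < 2L) {
      stop("need at least two synonymous variants for scaling")
    }
    r$scaled <- r$ratio - stats::median(syn)
    r
  })
  key <- function(d) paste(d$position, d$codon, sep = "\r")
  keys <- lapply(scaled, key)
  all_k <- Reduce(union, keys)
  sc_mat <- vapply(seq_along(scaled), function(i) {
    scaled[[i]]$scaled[match(all_k, keys[[i]])]
  }, numeric(length(all_k)))
  ratio_mat <- vapply(seq_along(scaled), function(i) {
    scaled[[i]]$ratio[match(all_k, keys[[i]])]
  }, numeric(length(all_k)))
  sc_mat <- matrix(sc_mat, nrow = length(all_k))
  ratio_mat <- matrix(ratio_mat, nrow = length(all_k))
  first <- scaled[[1L]][match(all_k, keys[[1L]]), ]
  out <- data.frame(position = first$position, codon = first$codon,
                    aa = first$aa, wt_aa = first$wt_aa,
                    is_wt = first$is_wt,
                    is_synonymous = first$is_synonymous,
                    ratio = rowMeans(ratio_mat, na.rm = TRUE),
                    dms_score = rowMeans(sc_mat, na.rm = TRUE),
                    n_replicates = rowSums(!is.na(sc_mat)),
                    stringsAsFactors = FALSE)
  # final re-centering: pooled synonymous median is exactly 0
  out$dms_score <- out$dms_score -
    stats::median(out$dms_score[out$is_synonymous])
  out[order(out$position, out$codon), , drop = FALSE]
}

# empirical percentile thresholds of the codon-level synonymous distribution
synonymous_thresholds <- function(scores, pct_low = 1, pct_high = 99) {
  syn <- scores$dms_score[scores$is_synonymous]
  if (length(syn) < 10L) {
    warning("only ", length(syn),
            " synonymous variants; percentile thresholds are unstable")
  }
  stats::quantile(syn, c(pct_low, pct_high) / 100, names = FALSE)
}

#' Classify variants against the synonymous score distribution
#'
#' Variants with a DMS score strictly below the synonymous distribution's
#' 1st percentile are called \code{deleterious}; strictly above the 99th
#' percentile, \code{improving}; otherwise \code{neutral}. Percentiles use
#' linear interpolation at the codon level.
#'
#' @param scores Variant scores from [dms_scores()].
#' @param pct_low,pct_high Percentile bounds (defaults 1 and 99).
#' @return The score table with a \code{class} column; thresholds attached
#'   as attribute \code{"thresholds"}.
#' @export
classify_variants <- function(scores, pct_low = 1, pct_high = 99) {
  thr <- synonymous_thresholds(scores, pct_low, pct_high)
  scores$class <- ifelse(scores$dms_score < thr[1L], "deleterious",
                  ifelse(scores$dms_score > thr[2L], "improving", "neutral"))
  attr(scores, "thresholds") <- c(low = thr[1L], high = thr[2L])
  scores
}

#' Aggregate codon-level scores to amino-acid substitutions
#'
#' The score of a substitution (position, aa) is the mean DMS score over
#' all codons encoding it, excluding the wild-type codon itself. Stop-codon
#' substitutions are scored but flagged so heatmaps can drop them.
#'
#' @param scores Variant scores from [dms_scores()].
#' @return Data frame with \code{position}, \code{aa}, \code{wt_aa},
#'   \code{score}, \code{n_codons}, \code{is_stop}.
#' @export
aggregate_to_aa <- function(scores) {
  s <- scores[!scores$is_wt, , drop = FALSE]
  grp <- interaction(s$position, s$aa, drop = TRUE, sep = "\r")
  agg <- tapply(s$dms_score, grp, mean)
  n <- tapply(s$dms_score, grp, length)
  labels <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  pos <- as.integer(labels[, 1L])
  wt_map <- tapply(s$wt_aa, s$position, `[`, 1L)
  out <- data.frame(position = pos, aa = labels[, 2L],
                    wt_aa = unname(wt_map[as.character(pos)]),
                    score = as.numeric(agg), n_codons = as.integer(n),
                    is_stop = labels[, 2L] == "*",
                    stringsAsFactors = FALSE)
  out[order(out$position, out$aa), , drop = FALSE]
}

#' Cross-classify substitutions by their effect on two interactions
#'
#' For two interaction partners scored on the same mutant library, each
#' amino-acid substitution is destabilizing for a partner when its aa-level
#' score lies below that partner's own synonymous 1st percentile. The four
#' resulting categories partition all substitutions: destabilizing both,
#' destabilizing only the first or only the second, and neutral-or-
#' increasing.
#'
#' @param scores_ppi1,scores_ppi2 Codon-level variant scores
#'   ([dms_scores()]) for the two interactions.
#' @param thresholds Optional numeric length-2 vector overriding the two
#'   synonymous 1st-percentile thresholds.
#' @param labels Character length-2 partner names used in category labels.
#' @return Data frame with \code{position}, \code{aa}, the two aa-level
#'   scores, and \code{category}. Substitutions missing from one partner
#'   are excluded with a message.
#' @export
assign_categories <- function(scores_ppi1, scores_ppi2, thresholds = NULL,
                              labels = c("ppi1", "ppi2")) {
  if (is.null(thresholds)) {
    thresholds <- c(synonymous_thresholds(scores_ppi1)[1L],
                    synonymous_thresholds(scores_ppi2)[1L])
  }
  a1 <- aggregate_to_aa(scores_ppi1)
  a2 <- aggregate_to_aa(scores_ppi2)
  k1 <- paste(a1$position, a1$aa, sep = "\r")
  k2 <- paste(a2$position, a2$aa, sep = "\r")
  common <- intersect(k1, k2)
  n_drop <- length(union(k1, k2)) - length(common)
  if (n_drop > 0L) {
    message(n_drop, " substitution(s) missing from one interaction; excluded")
  }
  s1 <- a1$score[match(common, k1)]
  s2 <- a2$score[match(common, k2)]
  below1 <- s1 < thresholds[1L]
  below2 <- s2 < thresholds[2L]
  category <- ifelse(below1 & below2, "destabilize_both",
              ifelse(below1, paste0("destabilize_", labels[1L], "_only"),
              ifelse(below2, paste0("destabilize_", labels[2L], "_only"),
                     "neutral_or_increasing")))
  out <- data.frame(position = a1$position[match(common, k1)],
                    aa = a1$aa[match(common, k1)],
                    score_ppi1 = s1, score_ppi2 = s2,
                    category = category, stringsAsFactors = FALSE)
  names(out)[3:4] <- paste0("score_", labels)
  attr(out, "thresholds") <- stats::setNames(thresholds, labels)
  out[order(out$position, out$aa), , drop = FALSE]
}
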