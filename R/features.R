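# Feature engineering: the volcano-style channel enrichment screen
# (Fisher's exact test with Benjamini-Hochberg correction plus a
# fold-change threshold on group-mean proportions) and aggregation of the
# enriched channels into the six genomic features used by the classifier.

FEATURE_ORDER <- c("loh_1_40mb", "del5_mh", "het_3_9_10_40mb",
                   "ncgt", "nctg", "het_2_4_gt40mb")

#' Screen channels for HRD/HRP enrichment
#'
#' For every channel of a context matrix, computes (a) the log2 fold change
#' between the HRD and HRP group means of the per-sample channel
#' proportions (a pseudocount of 1e-6 on each mean avoids infinities), and
#' (b) a two-sided Fisher exact p-value on the pooled 2x2 table of
#' channel-versus-all-other-channel event counts in the two groups.
#' P-values are Benjamini-Hochberg adjusted across the channels of the
#' class, and a channel is flagged as enriched in one group when its
#' absolute log2 fold change exceeds `fc_threshold` and
#' `-log10(q) > fdr_log_threshold`.
#'
#' @param matrix A [context_matrix()].
#' @param labels Named character vector (or factor) mapping every sample
#'   column to `"HRD"` or `"HRP"`.
#' @param fc_threshold Absolute log2 fold-change threshold: 0.75 for
#'   whole-genome data, 0.25 for whole-exome data.
#' @param fdr_log_threshold Threshold on `-log10` of the adjusted p-value
#'   (default 3).
#' @return Tibble with one row per channel: `channel`, `variant_class`,
#'   `log2_fc`, `p_value`, `q_value`, `enriched_in` (`"HRD"`, `"HRP"` or
#'   `"none"`), in canonical channel order.
#' @export
channel_enrichment <- function(matrix, labels, fc_threshold = 0.75,
                               fdr_log_threshold = 3) {
  labels <- labels[colnames(matrix)]
  if (anyNA(labels)) stop("every sample column must have an HRD/HRP label")
  labels <- as.character(labels)
  stopifnot(all(labels %in% c("HRD", "HRP")))
  if (!any(labels == "HRD") || !any(labels == "HRP")) {
    stop("both label groups must be non-empty")
  }
  m <- unclass_matrix(matrix)
  totals <- colSums(m)
  for (g in c("HRD", "HRP")) {
    if (sum(totals[labels == g]) == 0) {
      stop("group ", g, " has zero total events in this class")
    }
  }
  props <- sweep(m, 2, pmax(totals, 1), "/")
  mean_hrd <- rowMeans(props[, labels == "HRD", drop = FALSE])
  mean_hrp <- rowMeans(props[, labels == "HRP", drop = FALSE])
  eps <- 1e-6
  log2_fc <- log2((mean_hrd + eps) / (mean_hrp + eps))

  pooled_hrd <- rowSums(m[, labels == "HRD", drop = FALSE])
  pooled_hrp <- rowSums(m[, labels == "HRP", drop = FALSE])
  tot_hrd <- sum(pooled_hrd); tot_hrp <- sum(pooled_hrp)
  p_value <- vapply(seq_len(nrow(m)), function(i) {
    stats::fisher.test(matrix(c(pooled_hrd[i], tot_hrd - pooled_hrd[i],
                                pooled_hrp[i], tot_hrp - pooled_hrp[i]),
                              nrow = 2))$p.value
  }, numeric(1))
  q_value <- stats::p.adjust(p_value, method = "BH")
  sig <- abs(log2_fc) > fc_threshold & -log10(q_value) > fdr_log_threshold
  tibble::tibble(
    channel = rownames(m),
    variant_class = attr(matrix, "variant_class"),
    log2_fc = log2_fc,
    p_value = p_value,
    q_value = q_value,
    enriched_in = dplyr::case_when(
      sig & log2_fc > 0 ~ "HRD",
      sig & log2_fc < 0 ~ "HRP",
      TRUE ~ "none"
    )
  )
}

#' Extract the six HRD-predictive features per sample
#'
#' The six features aggregate the channels found enriched in HRD or HRP
#' tumours:
#' * `loh_1_40mb` - proportion of copy-number segments with LOH (minor copy
#'   number 0, TCN >= 1) and size in (1, 40] Mb;
#' * `del5_mh` - deletions of at least 5 bp at microhomologies
#'   (ID-83 channels `5:Del:M:1-5`): proportion of indel events for
#'   whole-genome data, absolute count for whole-exome data;
#' * `het_3_9_10_40mb` - proportion of heterozygous segments with TCN in
#'   [3, 9] and size in (10, 40] Mb;
#' * `ncgt` - proportion of substitutions in the `N[C>G]T` channels;
#' * `nctg` - proportion of substitutions in the `N[C>T]G` channels;
#' * `het_2_4_gt40mb` - proportion of heterozygous segments with TCN in
#'   [2, 4] and size > 40 Mb.
#'
#' Copy-number features filter on the raw TCN and size of each segment (not
#' on the binned CN-48 channel), with the total number of the sample's
#' segments as denominator.  A zero denominator yields 0 with a warning.
#'
#' @param sbs,id [context_matrix()] objects (SBS96 and ID83) sharing a
#'   sample set.
#' @param segments Segment table ([segment_records()]).
#' @param assay `"WGS"` or `"WES"`; controls the `del5_mh` convention.
#' @param del5_as_count Override for the `del5_mh` convention; defaults to
#'   counts for WES and proportions for WGS.
#' @param samples Optional sample set/order; defaults to the union of the
#'   matrix columns.
#' @return Tibble with one row per sample: `sample_id`, `assay`, and the
#'   six feature columns.
#' @export
extract_features <- function(sbs, id, segments, assay = c("WGS", "WES"),
                             del5_as_count = NULL, samples = NULL) {
  assay <- match.arg(assay)
  if (is.null(del5_as_count)) del5_as_count <- (assay == "WES")
  if (is.null(samples)) samples <- union(colnames(sbs), colnames(id))

  safe_prop <- function(num, den, what) {
    zero <- den == 0 & num >= 0
    if (any(zero & num >= 0) && any(den == 0)) {
      warning("zero ", what, " total for sample(s): ",
              paste(utils::head(samples[den == 0], 5), collapse = ", "))
    }
    ifelse(den == 0, 0, num / den)
  }

  sbs_m <- unclass_matrix(sbs)[, samples, drop = FALSE]
  id_m <- unclass_matrix(id)[, samples, drop = FALSE]
  sbs_tot <- colSums(sbs_m)
  id_tot <- colSums(id_m)
  nctg <- safe_prop(colSums(sbs_m[NCTG_CHANNELS, , drop = FALSE]), sbs_tot, "SBS")
  ncgt <- ifelse(sbs_tot == 0, 0,
                 colSums(sbs_m[NCGT_CHANNELS, , drop = FALSE]) / pmax(sbs_tot, 1))
  del5_raw <- colSums(id_m[DEL5_MH_CHANNELS, , drop = FALSE])
  del5 <- if (del5_as_count) del5_raw else
    safe_prop(del5_raw, id_tot, "indel")

  seg <- segments[segments$sample_id %in% samples, ]
  seg_tot <- table(factor(seg$sample_id, levels = samples))
  count_seg <- function(cond) {
    as.numeric(table(factor(seg$sample_id[cond], levels = samples)))
  }
  loh <- count_seg(seg$minor_cn == 0 & seg$tcn >= 1 &
                     seg$size > 1e6 & seg$size <= 4e7)
  het39 <- count_seg(seg$minor_cn >= 1 & seg$tcn >= 3 & seg$tcn <= 9 &
                       seg$size > 1e7 & seg$size <= 4e7)
  het24 <- count_seg(seg$minor_cn >= 1 & seg$tcn >= 2 & seg$tcn <= 4 &
                       seg$size > 4e7)
  den <- as.numeric(seg_tot)
  tibble::tibble(
    sample_id = samples,
    assay = assay,
    loh_1_40mb = safe_prop(loh, den, "segment"),
    del5_mh = unname(del5),
    het_3_9_10_40mb = ifelse(den == 0, 0, het39 / pmax(den, 1)),
    ncgt = unname(ncgt),
    nctg = unname(nctg),
    het_2_4_gt40mb = ifelse(den == 0, 0, het24 / pmax(den, 1))
  )
}
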