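#' ChIP-qPCR enrichment: percent input and fold over the negative region
#'
#' Percent input follows standard base-2 chemistry with a dilution
#' adjustment for the input fraction:
#' `percent_input = 100 * 2^((ct_input - log2(1/input_fraction)) - ct_ip)`.
#' Fold over negative divides each record's percent input by the percent
#' input of the matched negative-control record (same antibody, timepoint
#' and replicate).
#'
#' @param records data.frame with columns target, antibody, timepoint_h,
#'   replicate, ct_ip, ct_input (see [simulate_qpcr()] /
#'   [read_qpcr_table()]).
#' @param input_fraction fraction of chromatin kept as input, in (0, 1].
#' @param negative_target name of the negative-control region
#'   (default "Untr6").
#' @return `records` with added percent_input and fold_over_negative
#'   columns; the negative target's fold over itself is exactly 1.
#' @export
qpcr_enrichment <- function(records, input_fraction = 1,
                            negative_target = "Untr6") {
  stopifnot(input_fraction > 0, input_fraction <= 1)
  need <- c("target", "antibody", "timepoint_h", "replicate", "ct_ip",
            "ct_input")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  ct_input_adj <- records$ct_input - log2(1 / input_fraction)
  records$percent_input <- 100 * 2^(ct_input_adj - records$ct_ip)
  key <- interaction(records$antibody, records$timepoint_h,
                     records$replicate, drop = TRUE)
  neg <- records$target == negative_target
  neg_pct <- records$percent_input[neg]
  names(neg_pct) <- as.character(key[neg])
  matched <- neg_pct[as.character(key)]
  if (anyNA(matched))
    stop("missing matched negative-control record for some conditions")
  records$fold_over_negative <- records$percent_input / matched
  records
}

#' Postmortem-interval stability: one-way ANOVA + Bonferroni post-hoc
#'
#' One-way fixed-effects ANOVA of an enrichment value across postmortem
#' timepoints, followed by all pairwise t comparisons with
#' Bonferroni-adjusted p-values (pooled SD, the classical post-hoc form).
#'
#' @param values numeric enrichment values (e.g. fold_over_negative).
#' @param timepoints matching timepoints (hours); coerced to factor.
#' @param alpha significance level for flags (default 0.05).
#' @param log2_scale test on log2(values) instead of the raw scale.
#' @return list: `F`, `p`, `df` (numerator/denominator), `pairwise`
#'   (data.frame t1, t2, p_raw, p_bonferroni, significant), `alpha`.
#' @export
stability_anova <- function(values, timepoints, alpha = 0.05,
                            log2_scale = FALSE) {
  tp <- factor(timepoints)
  if (nlevels(tp) < 2) stop("need >= 2 timepoints")
  if (any(table(tp) < 2)) stop("every timepoint needs >= 2 replicates")
  y <- if (log2_scale) log2(values) else values
  if (stats::sd(y) == 0) {
    fit_F <- 0
    fit_p <- 1
    dfs <- c(nlevels(tp) - 1, length(y) - nlevels(tp))
  } else {
    fit <- stats::aov(y ~ tp)
    s <- summary(fit)[[1]]
    fit_F <- s[["F value"]][1]
    fit_p <- s[["Pr(>F)"]][1]
    dfs <- s[["Df"]]
  }
  lev <- levels(tp)
  pairs <- utils::combn(lev, 2)
  n_pairs <- ncol(pairs)
  mse <- sum(tapply(y, tp, function(v) sum((v - mean(v))^2))) /
    (length(y) - nlevels(tp))
  p_raw <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    a <- y[tp == pairs[1, i]]
    b <- y[tp == pairs[2, i]]
    if (mse == 0) {
      p_raw[i] <- if (mean(a) == mean(b)) 1 else 0
    } else {
      tstat <- (mean(a) - mean(b)) /
        sqrt(mse * (1 / length(a) + 1 / length(b)))
      p_raw[i] <- 2 * stats::pt(-abs(tstat), df = length(y) - nlevels(tp))
    }
  }
  p_bonf <- pmin(1, p_raw * n_pairs)
  list(F = fit_F, p = fit_p, df = dfs[1:2],
       pairwise = data.frame(t1 = pairs[1, ], t2 = pairs[2, ],
                             p_raw = p_raw, p_bonferroni = p_bonf,
                             significant = p_bonf < alpha,
                             stringsAsFactors = FALSE),
       alpha = alpha)
}

#' Log-scale enrichment decay slope over postmortem time
#'
#' OLS slope (with intercept) of log2(fold over negative) on hours, per
#' antibody, pooling positive targets. An exact halving per 24 h gives a
#' slope of -1/24 per hour; a faster-decaying mark has a more negative
#' slope.
#'
#' @param enrichment data.frame from [qpcr_enrichment()].
#' @param negative_target negative-control region to exclude.
#' @return data.frame: antibody, slope (per hour), se, n.
#' @export
decay_slope <- function(enrichment, negative_target = "Untr6") {
  pos <- enrichment[enrichment$target != negative_target, ]
  rows <- lapply(split(pos, pos$antibody), function(d) {
    x <- d$timepoint_h
    y <- log2(d$fold_over_negative)
    sxx <- sum((x - mean(x))^2)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    res <- y - mean(y) - slope * (x - mean(x))
    se <- sqrt(sum(res^2) / (length(y) - 2) / sxx)
    data.frame(antibody = d$antibody[1], slope = slope, se = se,
               n = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
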