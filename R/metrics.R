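#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)`: 0 means no overlap, 1 perfect overlap. Two
#' empty masks are defined to agree perfectly (Dice 1).
#'
#' @param mask_a,mask_b congruent [binary_mask()] objects (or logical
#'   arrays of identical shape).
#' @return numeric in \[0, 1\].
#' @export
dice <- function(mask_a, mask_b) {
  a <- if (inherits(mask_a, "binary_mask")) mask_a$bits else mask_a
  b <- if (inherits(mask_b, "binary_mask")) mask_b$bits else mask_b
  if (!identical(dim(a), dim(b)))
    stop("mask shapes differ: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' 5x5 risk-category confusion matrix
#'
#' Rows are the reference grade, columns the predicted grade, over the
#' CAC-DRS categories 0/I/II/III/IV.
#'
#' @param reference,predicted equal-length grade vectors (values in
#'   `c("0","I","II","III","IV")`).
#' @return 5x5 integer matrix with grade dimnames.
#' @export
confusion <- function(reference, predicted) {
  if (length(reference) != length(predicted))
    stop("grade sequences have different lengths")
  bad <- !(reference %in% cac_grades) | !(predicted %in% cac_grades)
  if (any(bad))
    stop("grades outside 0/I/II/III/IV at positions: ",
         paste(which(bad), collapse = ", "))
  table(factor(reference, levels = cac_grades),
        factor(predicted, levels = cac_grades))
}

#' Cohen's kappa with a 95% confidence interval
#'
#' Unweighted kappa `(p_o - p_e) / (1 - p_e)` where `p_o` is the
#' observed (diagonal) agreement fraction and `p_e` the chance
#' agreement from the marginals. The confidence interval uses the
#' asymptotic standard error of Fleiss, Cohen and Everitt (normal
#' bounds, clipped to \[-1, 1\]); a seeded bootstrap over subjects is
#' available as a cross-check. Degenerate marginals with `p_e = 1`
#' leave kappa undefined, returned as `NA` with a `note`.
#'
#' @param cm square confusion matrix of counts (n >= 2).
#' @param conf_level confidence level, default 0.95.
#' @param method `"asymptotic"` (default) or `"bootstrap"`.
#' @param n_boot,seed bootstrap resamples and seed.
#' @return list with `kappa`, `ci_low`, `ci_high`, `n` and optionally
#'   `note`.
#' @export
cohen_kappa <- function(cm, conf_level = 0.95,
                        method = c("asymptotic", "bootstrap"),
                        n_boot = 2000L, seed = 0L) {
  method <- match.arg(method)
  cm <- as.matrix(cm)
  n <- sum(cm)
  if (n < 2) stop("need at least 2 subjects")
  p <- cm / n
  po <- sum(diag(p))
  rs <- rowSums(p); cs <- colSums(p)
  pe <- sum(rs * cs)
  if (1 - pe < 1e-12)
    return(list(kappa = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                n = n, note = "undefined: chance agreement is 1"))
  kappa <- (po - pe) / (1 - pe)
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (method == "asymptotic") {
    k <- nrow(p)
    a <- 0
    for (i in seq_len(k))
      a <- a + p[i, i] * (1 - (rs[i] + cs[i]) * (1 - kappa))^2
    b <- 0
    for (i in seq_len(k))
      for (j in seq_len(k))
        if (i != j) b <- b + p[i, j] * (cs[i] + rs[j])^2
    b <- b * (1 - kappa)^2
    cc <- (kappa - pe * (1 - kappa))^2
    se <- sqrt(max(0, a + b - cc)) / ((1 - pe) * sqrt(n))
    ci <- kappa + c(-1, 1) * z * se
  } else {
    ref <- rep(rep(seq_len(nrow(cm)), ncol(cm)), as.vector(cm))
    prd <- rep(rep(seq_len(ncol(cm)), each = nrow(cm)), as.vector(cm))
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    ks <- vapply(seq_len(n_boot), function(b) {
      s <- sample.int(n, n, replace = TRUE)
      cmb <- table(factor(ref[s], levels = seq_len(nrow(cm))),
                   factor(prd[s], levels = seq_len(ncol(cm))))
      pb <- cmb / n
      peb <- sum(rowSums(pb) * colSums(pb))
      if (1 - peb < 1e-12) NA_real_
      else (sum(diag(pb)) - peb) / (1 - peb)
    }, numeric(1))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    ci <- unname(stats::quantile(ks, c((1 - conf_level) / 2,
                                       1 - (1 - conf_level) / 2),
                                 na.rm = TRUE))
  }
  list(kappa = unname(kappa), ci_low = max(-1, ci[1]),
       ci_high = min(1, ci[2]), n = n)
}

#' Per-category diagnostic metrics
#'
#' One-vs-rest sensitivity, specificity, PPV, NPV and F1 for every
#' grade. Ratios with zero denominators are reported as `NA`
#' (not available), never coerced to 0, so sparse grades cannot
#' silently inflate or deflate a summary.
#'
#' @param cm square confusion matrix (rows reference, columns
#'   predicted).
#' @return data.frame with columns `grade`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `f1`.
#' @export
per_category_metrics <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  if (n < 1) stop("empty confusion matrix")
  grades <- rownames(cm)
  if (is.null(grades)) grades <- as.character(seq_len(nrow(cm)))
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  rows <- lapply(seq_len(nrow(cm)), function(g) {
    tp <- cm[g, g]
    fn <- sum(cm[g, ]) - tp
    fp <- sum(cm[, g]) - tp
    tn <- n - tp - fn - fp
    sens <- ratio(tp, tp + fn)
    spec <- ratio(tn, tn + fp)
    ppv <- ratio(tp, tp + fp)
    npv <- ratio(tn, tn + fn)
    f1 <- if (is.na(sens) || is.na(ppv) || sens + ppv == 0) NA_real_
          else 2 * ppv * sens / (ppv + sens)
    data.frame(grade = grades[g], sensitivity = sens, specificity = spec,
               ppv = ppv, npv = npv, f1 = f1)
  })
  do.call(rbind, rows)
}

#' Category agreement summary
#'
#' Fractions of subjects whose predicted grade matches the reference
#' exactly, is exactly one category off, or is more than one off (the
#' three sum to 1), plus over- and under-estimation fractions.
#'
#' @param cm square confusion matrix.
#' @return list with `exact`, `within_one`, `beyond_one`,
#'   `over_estimated`, `under_estimated`.
#' @export
agreement_summary <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  if (n < 1) stop("empty confusion matrix")
  k <- nrow(cm)
  dist <- abs(outer(seq_len(k), seq_len(k), "-"))
  over <- outer(seq_len(k), seq_len(k), function(r, p) p > r)
  list(exact = sum(diag(cm)) / n,
       within_one = sum(cm[dist == 1]) / n,
       beyond_one = sum(cm[dist > 1]) / n,
       over_estimated = sum(cm[over]) / n,
       under_estimated = sum(cm[t(over)]) / n)
}

#' Presence/absence diagnostics of calcification
#'
#' Binarizes total scores at "any calcium" (> 0) and reports the
#' sensitivity and specificity of predicted presence against reference
#' presence. A class absent from the reference leaves the corresponding
#' metric `NA`.
#'
#' @param reference_totals,predicted_totals equal-length numeric score
#'   vectors.
#' @return list with `sensitivity` and `specificity`.
#' @export
presence_metrics <- function(reference_totals, predicted_totals) {
  if (length(reference_totals) != length(predicted_totals))
    stop("score sequences have different lengths")
  rp <- reference_totals > 0
  pp <- predicted_totals > 0
  sens <- if (any(rp)) sum(pp & rp) / sum(rp) else NA_real_
  spec <- if (any(!rp)) sum(!pp & !rp) / sum(!rp) else NA_real_
  list(sensitivity = sens, specificity = spec)
}
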