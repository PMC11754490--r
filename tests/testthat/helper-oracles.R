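# Independent brute-force oracles the fast implementations are checked
# against. Everything here is deliberately naive (queue-based search,
# direct tallies) and shares no code with the package internals.

# Connected components by breadth-first search over an offset list.
bf_label_components <- function(bits, connectivity = 26L) {
  d <- dim(bits)
  off <- cacscore::se_offsets(1L, connectivity)
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  labels <- array(0L, d)
  nextl <- 0L
  for (i in which(bits)) {
    if (labels[i] > 0L) next
    nextl <- nextl + 1L
    queue <- i
    labels[i] <- nextl
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(cur, d)
      for (r in seq_len(nrow(off))) {
        p <- ijk + off[r, ]
        if (any(p < 1) || any(p > d)) next
        j <- p[1] + d[1] * (p[2] - 1) + d[1] * d[2] * (p[3] - 1)
        if (bits[j] && labels[j] == 0L) {
          labels[j] <- nextl
          queue <- c(queue, j)
        }
      }
    }
  }
  labels
}

# Per-voxel Agatston on a noise-free phantom, restricted to the truth
# lesion voxels: label each lesion's slices in 2D (8-connectivity) and
# accumulate area x coefficient of the component maximum.
bf_agatston <- function(truth, hu_min = 130) {
  spacing <- truth$heart$spacing
  d <- dim(truth$heart$bits)
  pix <- spacing[1] * spacing[2]
  coef <- function(m) {
    if (m >= 400) 4 else if (m >= 300) 3 else if (m >= 200) 2 else 1
  }
  scores <- c(RCA = 0, LAD = 0, LCX = 0, AORTA = 0)
  for (l in truth$lesions) {
    keep <- l$hu >= hu_min
    if (!any(keep)) next
    for (z in unique(l$slice[keep])) {
      sel <- which(keep & l$slice == z)
      sl <- array(FALSE, c(d[1], d[2], 1L))
      ijk <- arrayInd(l$idx[sel], d)
      sl[cbind(ijk[, 1:2, drop = FALSE], 1L)] <- TRUE
      lab <- bf_label_components(sl, 8L)
      comp <- lab[cbind(ijk[, 1:2, drop = FALSE], 1L)]
      for (k in unique(comp)) {
        m <- max(l$hu[sel][comp == k])
        scores[l$artery] <- scores[l$artery] + sum(comp == k) * pix * coef(m)
      }
    }
  }
  scores
}

# Agreement statistics recomputed directly from expanded subject pairs.
bf_pairs_from_cm <- function(cm) {
  k <- nrow(cm)
  ref <- rep(rep(seq_len(k), k), as.vector(cm))
  prd <- rep(rep(seq_len(k), each = k), as.vector(cm))
  cbind(ref, prd)
}

bf_kappa <- function(cm) {
  pr <- bf_pairs_from_cm(cm)
  n <- nrow(pr)
  po <- mean(pr[, 1] == pr[, 2])
  pe <- 0
  for (g in seq_len(nrow(cm)))
    pe <- pe + mean(pr[, 1] == g) * mean(pr[, 2] == g)
  (po - pe) / (1 - pe)
}

bf_one_vs_rest <- function(cm, g) {
  pr <- bf_pairs_from_cm(cm)
  tp <- sum(pr[, 1] == g & pr[, 2] == g)
  fn <- sum(pr[, 1] == g & pr[, 2] != g)
  fp <- sum(pr[, 1] != g & pr[, 2] == g)
  tn <- sum(pr[, 1] != g & pr[, 2] != g)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  f1 <- if (is.na(sens) || is.na(ppv) || sens + ppv == 0) NA_real_
        else 2 * sens * ppv / (sens + ppv)
  c(sens = sens, spec = spec, ppv = ppv, npv = npv, f1 = f1)
}

bf_agreement <- function(cm) {
  pr <- bf_pairs_from_cm(cm)
  diff <- pr[, 2] - pr[, 1]
  c(exact = mean(diff == 0), within_one = mean(abs(diff) == 1),
    beyond_one = mean(abs(diff) > 1), over = mean(diff > 0),
    under = mean(diff < 0))
}

random_cm5 <- function() {
  matrix(sample(0:12, 25, replace = TRUE), 5, 5,
         dimnames = list(c("0", "I", "II", "III", "IV"),
                         c("0", "I", "II", "III", "IV")))
}

# circular shift of a 3D array along axis 1/2, padding with `fill`
shift_array <- function(a, by, axis, fill) {
  d <- dim(a)
  out <- array(fill, d)
  if (by >= 0) {
    src <- seq_len(d[axis] - by); dst <- src + by
  } else {
    dst <- seq_len(d[axis] + by); src <- dst - by
  }
  if (axis == 1) out[dst, , ] <- a[src, , ]
  else out[, dst, ] <- a[, src, ]
  out
}
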