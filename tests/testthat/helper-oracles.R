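# Independent oracles and small fixture builders shared by the tests.

# AUC as the exhaustive concordant-pair fraction (ties = 1/2), with the
# given case-like orientation.
auc_by_pairs <- function(scores, is_case, orientation = "lower") {
  cs <- scores[is_case]; ct <- scores[!is_case]
  conc <- outer(cs, ct, function(a, b) {
    if (orientation == "lower") (a < b) + 0.5 * (a == b)
    else (a > b) + 0.5 * (a == b)
  })
  mean(conc)
}

# Two-sided Fisher p by explicit enumeration over the first cell,
# probabilities built from binomial coefficients (no dhyper).
fisher_by_enumeration <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, support) * choose(r2, c1 - support) /
    choose(r1 + r2, c1)
  p_obs <- probs[support == tab[1, 1]]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Youden-optimal operating point by brute force over a dense threshold
# grid including +/- eps around every observed score.
youden_by_grid <- function(scores, is_case, orientation = "lower") {
  eps <- 1e-9 * max(1, diff(range(scores)))
  grid <- sort(unique(c(scores, scores - eps, scores + eps)))
  best <- c(j = -Inf, sens = -Inf)
  for (t in grid) {
    pos <- if (orientation == "lower") scores <= t else scores >= t
    sens <- mean(pos[is_case]); spec <- mean(!pos[!is_case])
    j <- sens + spec - 1
    if (j > best["j"] + 1e-12 ||
        (abs(j - best["j"]) <= 1e-12 && sens > best["sens"] + 1e-12))
      best <- c(j = j, sens = sens)
  }
  best
}

# One-sample Ct table with explicit calibrator.
tiny_ct_table <- function(sdc2, tfpi2, actb,
                          calibrator = c(SDC2 = 30, TFPI2 = 30, ACTB = 28)) {
  ct_table(data.frame(sample_id = "S1",
                      gene = c("SDC2", "TFPI2", "ACTB"),
                      ct = c(sdc2, tfpi2, actb),
                      stringsAsFactors = FALSE),
           calibrator = calibrator)
}

extdata <- function(f) system.file("extdata", f, package = "dualmeth")
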