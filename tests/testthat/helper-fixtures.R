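# Fixtures and independent brute-force oracles used across test files.
# All fixtures are built in code; nothing is read from disk.

# A 92-case cohort reproducing the published bookkeeping: 8 auto-negative,
# 22 auto-positive, 62 uncertain (28 approved / 34 denied after escalation),
# and a reference-panel verdict distribution of 19/16/12/45 cases with
# 0/1/2/3 positive verdicts (57 reference positives).
make_printed_cohort <- function() {
  score <- c(rep(20, 8), rep(80, 22), rep(50, 28), rep(40, 34))
  iv1 <- c(rep(NA, 30), rep(1, 28), rep(0, 34))
  iv2 <- iv1
  ref_counts <- c(rep(0, 19), rep(1, 16), rep(2, 12), rep(3, 45))
  ref <- t(vapply(ref_counts, function(k) c(rep(1L, k), rep(0L, 3 - k)),
                  integer(3)))
  data.frame(
    case_id = sprintf("fx_%03d", 1:92),
    true_status = NA_integer_,
    ai_score = score,
    ct_compatible = 1L, dlco_available = 1L,
    ref_verdict_1 = ref[, 1], ref_verdict_2 = ref[, 2],
    ref_verdict_3 = ref[, 3],
    index_verdict_1 = iv1, index_verdict_2 = iv2,
    stringsAsFactors = FALSE
  )
}

# Index/reference label pair with confusion counts tp=49, fn=8, tn=30, fp=5.
make_confusion_fixture <- function() {
  list(
    pred = c(rep(1, 49), rep(0, 8), rep(0, 30), rep(1, 5)),
    ref  = c(rep(1, 49), rep(1, 8), rep(0, 30), rep(0, 5))
  )
}

random_ratings <- function(n, m, p = 0.5) {
  matrix(rbinom(n * m, 1, p), nrow = n, ncol = m)
}

# --- independent oracles -----------------------------------------------------

# mean pairwise agreement by explicit loops over items and rater pairs
oracle_pairwise_agreement <- function(R) {
  m <- ncol(R)
  total <- 0
  for (i in seq_len(nrow(R))) {
    agree <- 0
    for (a in 1:(m - 1)) for (b in (a + 1):m) {
      agree <- agree + (R[i, a] == R[i, b])
    }
    total <- total + agree / choose(m, 2)
  }
  total / nrow(R)
}

oracle_randolph <- function(R, c_ = 2) {
  po <- oracle_pairwise_agreement(R)
  (po - 1 / c_) / (1 - 1 / c_)
}

# textbook Fleiss kappa computed from category count tables
oracle_fleiss <- function(R) {
  m <- ncol(R); n <- nrow(R)
  cats <- sort(unique(as.vector(R)))
  nik <- sapply(cats, function(k) rowSums(R == k))
  nik <- matrix(nik, nrow = n)
  p_i <- (rowSums(nik^2) - m) / (m * (m - 1))
  p_k <- colSums(nik) / (n * m)
  (mean(p_i) - sum(p_k^2)) / (1 - sum(p_k^2))
}

# AUC by explicit loop over all positive/negative pairs
oracle_auc_pairs <- function(scores, ref) {
  pos <- scores[ref == 1]; neg <- scores[ref == 0]
  total <- 0
  for (x in pos) for (y in neg) {
    total <- total + (x > y) + 0.5 * (x == y)
  }
  total / (length(pos) * length(neg))
}

# average precision by enumerating every distinct threshold
oracle_average_precision <- function(scores, ref) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(ref == 1)
  prev_recall <- 0
  ap <- 0
  for (t in thresholds) {
    sel <- scores >= t
    tp <- sum(ref[sel] == 1)
    recall <- tp / n_pos
    precision <- tp / sum(sel)
    ap <- ap + precision * (recall - prev_recall)
    prev_recall <- recall
  }
  ap
}

# Kendall tau-b by explicit concordant/discordant pair counting
oracle_kendall_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tie_x <- tie_y <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
    if (dx == 0 && dy == 0) { tie_x <- tie_x + 1; tie_y <- tie_y + 1 }
    else if (dx == 0) tie_x <- tie_x + 1
    else if (dy == 0) tie_y <- tie_y + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tie_x) * (n0 - tie_y))
}
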