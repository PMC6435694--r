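# Independent brute-force oracles used to check the package's encoders and
# metrics. These deliberately share no code with the implementation.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

oracle_aac <- function(s) {
  ch <- strsplit(s, "")[[1]]
  out <- vapply(AA20, function(a) sum(ch == a), 0)
  100 * out / length(ch)
}

oracle_dpc <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  pairs <- paste0(ch[-n], ch[-1])
  lv <- c(t(outer(AA20, AA20, paste0)))
  out <- vapply(lv, function(d) sum(pairs == d), 0)
  100 * out / (n - 1)
}

# AUROC by exhaustive pair counting (ties count half)
oracle_auroc <- function(scores, is_pos) {
  ps <- scores[is_pos]
  ns <- scores[!is_pos]
  tot <- 0
  for (p in ps) for (q in ns) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(ps) * length(ns))
}

# number of peptides in `seqs` containing `pattern` as substring
oracle_support <- function(pattern, seqs) {
  sum(vapply(seqs, function(s) grepl(pattern, s, fixed = TRUE), logical(1)))
}

random_peptides <- function(n, min_len = 5, max_len = 80, seed = 1) {
  set.seed(seed)
  lens <- if (min_len == max_len) rep(min_len, n)
          else sample(min_len:max_len, n, replace = TRUE)
  vapply(lens, function(L) {
    paste(sample(AA20, L, replace = TRUE), collapse = "")
  }, "")
}

# tiny linearly separable toy: positives near (1, 0), negatives near (0, 1)
separable_toy <- function(n_per_class = 10, seed = 1) {
  set.seed(seed)
  x <- rbind(cbind(1 + rnorm(n_per_class, sd = 0.05),
                   rnorm(n_per_class, sd = 0.05)),
             cbind(rnorm(n_per_class, sd = 0.05),
                   1 + rnorm(n_per_class, sd = 0.05)))
  colnames(x) <- c("f1", "f2")
  list(x = x, labels = rep(c(TRUE, FALSE), each = n_per_class))
}
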