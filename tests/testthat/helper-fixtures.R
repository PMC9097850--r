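# Block fixtures built in code.

# A block of n samples x g genes with random Ct values; the first half of
# the samples is SHAM, the second tMCAO.
rand_block <- function(n = 8, g = 4, seed = 1, baseline = 20, sd = 1,
                       genes = paste0("G", seq_len(g))) {
  set.seed(seed)
  ct <- matrix(rnorm(n * g, baseline, sd), n, g,
               dimnames = list(paste0("s", seq_len(n)), genes))
  ct <- pmax(ct, 12)
  make_block(ct)
}

# Wrap a bare Ct matrix into a single-block ct_matrix (CX, 12h).
make_block <- function(ct, condition = NULL) {
  n <- nrow(ct)
  if (is.null(condition)) {
    condition <- rep(c("SHAM", "tMCAO"), c(ceiling(n / 2), floor(n / 2)))
  }
  if (is.null(rownames(ct))) rownames(ct) <- paste0("s", seq_len(n))
  m <- ct_matrix(ct, condition, rep("12h", n), rep("CX", n))
  slice_block(m, "CX", "12h")
}

# Small complete study with writable Ct table, for the IO tests.
study_fixture <- function(seed = 42) {
  simulate_ct(tmcao_preset(), seed = seed)
}
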