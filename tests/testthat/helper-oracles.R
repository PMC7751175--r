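# Independent brute-force oracles and small fixture builders used across
# the suite. The oracles are deliberately naive per-column loops, written
# without reference to the package implementations.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# naive per-column substitution counter (gap = "-", "X" missing)
brute_substitutions <- function(sa, sb) {
  va <- strsplit(sa, "")[[1]]
  vb <- strsplit(sb, "")[[1]]
  n <- 0L
  for (i in seq_along(va)) {
    if (va[i] != "-" && vb[i] != "-" && va[i] != "X" && vb[i] != "X" &&
        va[i] != vb[i]) {
      n <- n + 1L
    }
  }
  n
}

brute_matrix <- function(seqs) {
  n <- length(seqs)
  m <- matrix(0L, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- brute_substitutions(seqs[[i]], seqs[[j]])
    }
  }
  m
}

# naive per-column classifier mirroring the documented rules
brute_classify <- function(seqs, groups, focal_nc4, focal_c4, ref_id) {
  va <- strsplit(seqs[[focal_nc4]], "")[[1]]
  vb <- strsplit(seqs[[focal_c4]], "")[[1]]
  vr <- strsplit(seqs[[ref_id]], "")[[1]]
  nc4 <- names(groups)[groups == "non-C4"]
  c4 <- names(groups)[groups == "C4"]
  out <- NULL
  pos <- 0L
  for (col in seq_along(va)) {
    if (vr[col] != "-") pos <- pos + 1L
    ok <- va[col] != "-" && vb[col] != "-" && va[col] != "X" &&
      vb[col] != "X" && va[col] != vb[col]
    if (!ok) next
    nc4_res <- vapply(nc4, function(id) strsplit(seqs[[id]], "")[[1]][col],
                      character(1))
    nc4_res <- nc4_res[nc4_res != "-" & nc4_res != "X"]
    c4_res <- vapply(c4, function(id) strsplit(seqs[[id]], "")[[1]][col],
                     character(1))
    c4_res <- c4_res[c4_res != "-" & c4_res != "X"]
    out <- rbind(out, data.frame(
      reference_position = pos,
      c4_state = if (vb[col] %in% nc4_res) "ancestral" else "novel",
      fixation = if (length(c4_res) > 0 && all(c4_res == vb[col]))
        "fixed" else "polymorphic",
      stringsAsFactors = FALSE))
  }
  out
}

# random toy protein panel with a gapless reference; occasional gaps and
# ambiguity characters elsewhere
random_panel_seqs <- function(n_seqs = 5, len = 30, gap_p = 0.08,
                              amb_p = 0.03) {
  ids <- c("REF", paste0("s", seq_len(n_seqs - 1)))
  seqs <- lapply(ids, function(id) {
    v <- sample(AA20, len, replace = TRUE)
    if (id != "REF") {
      v[stats::runif(len) < gap_p] <- "-"
      v[stats::runif(len) < amb_p] <- "X"
    }
    paste(v, collapse = "")
  })
  stats::setNames(seqs, ids)
}

# small noiseless factorial design for exact parameter recovery
noiseless_design <- function(pep = c(10, 50, 150, 500, 1500, 5000),
                             hco3 = c(10, 50, 200, 800, 3000, 10000),
                             ...) {
  assay_design(pep_levels = pep, hco3_levels = hco3,
               inhibitor_levels = list(), n_runs = 1,
               n_technical_reps = 1, residual_hco3_true = 0,
               noise_cv = 0, noise_sd = 0, include_zero_hco3 = FALSE,
               include_blanks = FALSE, ...)
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
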