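# Small matrices built in code for unit tests.

make_mat <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("g%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-group matrix with one planted fully reversed pair among null genes.
planted_reversal_mat <- function(n_per_group = 30, n_null_genes = 20, seed = 1) {
  reosig:::with_seed(seed, {
    n <- 2 * n_per_group
    genes <- c("pa", "pb", sprintf("n%02d", seq_len(n_null_genes)))
    m <- matrix(exp(rnorm(length(genes) * n, 2, 1)), nrow = length(genes),
                dimnames = list(genes, sprintf("s%02d", seq_len(n))))
    ref <- seq_len(n_per_group)
    m["pa", ref] <- exp(5 + rnorm(n_per_group, 0, 0.1))
    m["pb", ref] <- exp(3 + rnorm(n_per_group, 0, 0.1))
    m["pa", -ref] <- exp(3 + rnorm(n_per_group, 0, 0.1))
    m["pb", -ref] <- exp(5 + rnorm(n_per_group, 0, 0.1))
    list(mat = m, ref = colnames(m)[ref], other = colnames(m)[-ref])
  })
}
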