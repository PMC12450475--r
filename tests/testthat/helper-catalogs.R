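# shared fixtures, built in code

# two-gene catalog with q = (0.01, 0.001), alpha = (0.6, 0.4)
toy_catalog <- function() {
  build_catalog(
    tibble::tibble(
      gene_id = c("a", "b"), length_bp = c(4000L, 400L),
      expression_raw = c(6, 4)
    ),
    genome_length = 1e5
  )
}

# single gene spanning the whole genome: q = 1/4, alpha = 1
whole_genome_catalog <- function() {
  build_catalog(
    tibble::tibble(gene_id = "g", length_bp = 1e6L, expression_raw = 1),
    genome_length = 1e6
  )
}

# small random catalog for property loops
random_catalog <- function(n_genes, seed) {
  set.seed(seed)
  build_catalog(
    tibble::tibble(
      gene_id = sprintf("g%03d", seq_len(n_genes)),
      length_bp = as.integer(round(runif(n_genes, 5e3, 5e5))),
      expression_raw = rlnorm(n_genes, 0, 1)
    ),
    genome_length = 1e9
  )
}

# independent brute-force oracle for the expectation: averages exact
# per-gene silencing probabilities without the package's vectorized path
oracle_expected_loss <- function(catalog, M) {
  total <- 0
  for (j in seq_len(nrow(catalog))) {
    p_silenced <- 1 - (1 - catalog$q[j])^M
    total <- total + catalog$alpha[j] * p_silenced
  }
  total
}

# independent OLS oracle via the normal equations
oracle_slope <- function(y) {
  x <- seq_along(y) - 1
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  beta[2]
}
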