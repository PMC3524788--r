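# Shared fixtures and independent oracles used across test files.

# Small deterministic dataset: `n_genes` x `n_samples`, balanced two classes,
# first `n_inf` genes shifted by `effect` in class B.
make_toy_dataset <- function(n_genes = 10, n_samples = 20, n_inf = 2,
                             effect = 2, seed = 42) {
  set.seed(seed)
  half <- n_samples %/% 2
  labels <- rep(c("A", "B"), c(half, n_samples - half))
  vals <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
  if (n_inf > 0)
    vals[seq_len(n_inf), labels == "B"] <- vals[seq_len(n_inf), labels == "B"] + effect
  labeled_expression_dataset(vals,
                             sprintf("g%02d", seq_len(n_genes)),
                             sprintf("s%02d", seq_len(n_samples)),
                             labels)
}

# Write a dataset to expression + label files; returns the two paths.
write_dataset_files <- function(data, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  expr <- file.path(dir, "expr.tsv")
  lab <- file.path(dir, "labels.tsv")
  tab <- cbind(gene_id = data$gene_ids, as.data.frame(data$values))
  write.table(tab, expr, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(id = data$sample_ids, cls = as.character(data$labels)),
              lab, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  list(expr = expr, labels = lab)
}

# Independent brute-force dual objective: explicit double summation over
# support-vector pairs, linear kernel, no shared code with the package path.
brute_dual_linear <- function(SV, coefs) {
  quad <- 0
  for (i in seq_len(nrow(SV)))
    for (j in seq_len(nrow(SV)))
      quad <- quad + coefs[i] * coefs[j] * sum(SV[i, ] * SV[j, ])
  sum(abs(coefs)) - 0.5 * quad
}

# Independent scan of the subset stopping rule, written as the predicate
# reads: first k with av[k] >= baseline and no larger value in the
# look-ahead window.
oracle_select_k <- function(av, v_baseline, window = 10) {
  avv <- ifelse(is.na(av), -Inf, av)
  for (k in 1:200) {
    if (avv[k] < v_baseline) next
    beaten <- FALSE
    for (l in k:min(k + window, 200))
      if (avv[l] > avv[k]) { beaten <- TRUE; break }
    if (!beaten) return(k)
  }
  200L
}
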