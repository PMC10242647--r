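# Small fixtures built in code.

# reduced synthetic world for fast module tests
small_spec <- function(seed = 1, ...) {
  args <- utils::modifyList(list(
    n_genes = 300L,
    clusters = data.frame(cell_type = c("B", "NK", "Mono"),
                          subcluster = c("B_C4", "NK_C1", "Mono_C1"),
                          stringsAsFactors = FALSE),
    n_cells_per_cluster = 60L,
    n_markers_per_cluster = 20L,
    n_bulk_samples_per_class = 20L,
    panel_size = 10L,
    n_true_sets = 2L, n_null_sets = 8L, set_size = 12L,
    seed = seed), list(...))
  do.call(synthetic_spec, args)
}

# deterministic hand-made bulk cohort: `strong` genes separate the classes
# perfectly, `noise` genes are pure noise
toy_bulk <- function(n_per_class = 6, strong = "gA", noise = c("gB", "gC", "gD"),
                     seed = 1) {
  set.seed(seed)
  genes <- c(strong, noise)
  n <- 2 * n_per_class
  X <- matrix(rnorm(length(genes) * n, sd = 0.5), length(genes), n,
              dimnames = list(genes, sprintf("s%02d", seq_len(n))))
  X[strong, seq_len(n_per_class)] <- X[strong, seq_len(n_per_class)] + 10
  meta <- data.frame(id = colnames(X),
                     class_label = rep(c("positive", "negative"),
                                       each = n_per_class),
                     stringsAsFactors = FALSE)
  cohort(expr_matrix(X, "lognorm"), meta)
}

expect_setequal_chr <- function(a, b) expect_setequal(as.character(a),
                                                      as.character(b))
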