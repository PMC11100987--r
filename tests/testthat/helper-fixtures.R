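# Shared fixtures: everything is built in code at test time.

pop_spec <- default_mlgm_spec()

# Small random PD matrix with controllable scale
rand_pd <- function(p, scale = 1) {
  a <- matrix(rnorm(p * p), p, p)
  crossprod(a) / p * scale + diag(0.5 * scale, p)
}

# Random small mlgm-like parameter set (unstructured), for oracle checks
rand_params <- function(p = 5) {
  list(sigma_w = rand_pd(p, 2), sigma_b = rand_pd(p, 1), mu = rnorm(p, 0, 2))
}

# Hand-built clustered dataset from a matrix of rows and cluster ids
manual_dataset <- function(y, cluster_id) {
  y <- as.matrix(y)
  colnames(y) <- paste0("V", seq_len(ncol(y)))
  df <- data.frame(
    cluster_id = cluster_id,
    member_id = stats::ave(cluster_id, cluster_id, FUN = seq_along),
    y, check.names = FALSE
  )
  structure(list(data = df, condition = NULL, seed = NA_integer_),
            class = "clustered_dataset")
}

# Small simulated dataset under the default population model
small_dataset <- function(seed = 1, ng = 10, small = 2, large = 6) {
  simulate_dataset(pop_spec, design_condition(ng, small, large), seed)
}
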