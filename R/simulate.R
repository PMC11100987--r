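#' Unbalanced design condition
#'
#' A cell of the study design: `n_groups` clusters, exactly half of size
#' `small_size` and half of size `large_size`. In the standard grid the
#' large size is three times the small one, which fixes the coefficient of
#' variation of cluster sizes at 0.5 (a moderate degree of imbalance).
#'
#' @param n_groups Even number of clusters (NG).
#' @param small_size,large_size The two cluster sizes.
#' @param label Optional condition label; defaults to `"NG<ng>_GS<s>_<L>"`.
#' @return A `design_condition` object.
#' @export
design_condition <- function(n_groups, small_size, large_size, label = NULL) {
  n_groups <- as.integer(n_groups)
  if (n_groups < 2L || n_groups %% 2L != 0L) {
    stop("`n_groups` must be even (half small, half large clusters)", call. = FALSE)
  }
  if (small_size < 1L || large_size < small_size) {
    stop("need 1 <= small_size <= large_size", call. = FALSE)
  }
  if (is.null(label)) {
    label <- sprintf("NG%d_GS%d_%d", n_groups, small_size, large_size)
  }
  structure(
    list(n_groups = n_groups, small_size = as.integer(small_size),
         large_size = as.integer(large_size), label = label),
    class = "design_condition"
  )
}

#' The nine-cell study grid
#'
#' Number of groups in {50, 100, 200} crossed with unbalanced group sizes
#' 5/15, 10/30 and 25/75 (average sizes 10, 20 and 50; large = 3 x small in
#' every cell).
#'
#' @return Named list of [design_condition()]s in column-major grid order
#'   (GS varying fastest within NG).
#' @export
default_conditions <- function() {
  grid <- expand.grid(gs = 1:3, ng = c(50L, 100L, 200L))
  sizes <- list(c(5L, 15L), c(10L, 30L), c(25L, 75L))
  out <- lapply(seq_len(nrow(grid)), function(i) {
    s <- sizes[[grid$gs[i]]]
    design_condition(grid$ng[i], s[1], s[2])
  })
  names(out) <- vapply(out, `[[`, "", "label")
  out
}

#' Coefficient of variation of cluster sizes
#'
#' Population CV over the two size classes:
#' \eqn{\sqrt{((s-m)^2 + (L-m)^2)/2}/m} with \eqn{m = (s+L)/2}. Equals 0.5
#' exactly whenever the large size is triple the small one.
#'
#' @param condition A [design_condition()].
#' @return A single number.
#' @export
size_cv <- function(condition) {
  s <- condition$small_size
  L <- condition$large_size
  m <- (s + L) / 2
  sqrt(((s - m)^2 + (L - m)^2) / 2) / m
}

#' Cluster sizes of a condition
#'
#' Deterministic assignment: the first half of the clusters are small, the
#' rest large. Order is irrelevant to every downstream statistic because
#' clusters are exchangeable.
#'
#' @param condition A [design_condition()].
#' @return Integer vector of length `n_groups`.
#' @export
draw_cluster_sizes <- function(condition) {
  g <- condition$n_groups
  rep(c(condition$small_size, condition$large_size), each = g / 2L)
}

# Symmetric square root of a PSD matrix; tolerates exact zeros on the
# diagonal (degenerate latent distributions are legal inputs).
psd_sqrt <- function(m, tol = 1e-10) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vals <- e$values
  if (min(vals) < -tol * max(abs(vals), 1)) {
    stop("matrix is not positive semidefinite", call. = FALSE)
  }
  e$vectors %*% (sqrt(pmax(vals, 0)) * t(e$vectors))
}

#' Simulate a clustered dataset from an MLGM specification
#'
#' For each cluster draws growth factors \eqn{\eta_B \sim N(\alpha_B,
#' \Phi_B)} and residuals \eqn{\epsilon_B \sim N(0, \Theta_B)}, forming the
#' cluster component \eqn{b_g = \Lambda\eta_B + \epsilon_B}; each member
#' then adds an independent within-level draw
#' \eqn{\Lambda\eta_W + \epsilon_W}. The same seed reproduces the dataset
#' exactly.
#'
#' @param spec An [mlgm_spec()].
#' @param condition A [design_condition()].
#' @param seed Integer seed.
#' @return A `clustered_dataset`: a `data` data.frame with columns
#'   `cluster_id`, `member_id`, `V1..VT`, plus the condition and seed.
#' @export
simulate_dataset <- function(spec, condition, seed) {
  stopifnot(inherits(spec, "mlgm_spec"), inherits(condition, "design_condition"))
  lam <- spec$basis$loading_matrix
  tt <- nrow(lam)
  sizes <- draw_cluster_sizes(condition)
  g <- length(sizes)
  n_total <- sum(sizes)

  phi_b_half <- psd_sqrt(spec$between$latent_cov)
  phi_w_half <- psd_sqrt(spec$within$latent_cov)
  sd_b <- sqrt(spec$between$residual_var)
  sd_w <- sqrt(spec$within$residual_var)
  q <- ncol(lam)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  # cluster components, one column per cluster
  eta_b <- spec$between$latent_mean + phi_b_half %*% matrix(rnorm(q * g), q, g)
  b <- lam %*% eta_b + sd_b * matrix(rnorm(tt * g), tt, g)
  # member components, one column per individual
  eta_w <- phi_w_half %*% matrix(rnorm(q * n_total), q, n_total)
  w <- lam %*% eta_w + sd_w * matrix(rnorm(tt * n_total), tt, n_total)

  cluster_id <- rep.int(seq_len(g), sizes)
  y <- t(w + b[, cluster_id, drop = FALSE])
  colnames(y) <- paste0("V", seq_len(tt))
  df <- data.frame(
    cluster_id = cluster_id,
    member_id = sequence(sizes),
    y,
    check.names = FALSE
  )
  structure(list(data = df, condition = condition, seed = as.integer(seed)),
            class = "clustered_dataset")
}

.dataset_matrix <- function(dataset) {
  as.matrix(dataset$data[, grep("^V", names(dataset$data)), drop = FALSE])
}

#' Pooled within-cluster sample covariance
#'
#' \eqn{S_{PW} = \sum_g\sum_i (y_{gi}-\bar y_g)(y_{gi}-\bar y_g)'/(N-G)}:
#' the cluster-mean-centred scatter pooled over all clusters, which remains
#' a consistent estimate of \eqn{\Sigma_W} whether or not the design is
#' balanced.
#'
#' @param dataset A [simulate_dataset()] result (or compatible list).
#' @return T x T matrix.
#' @export
pooled_within_cov <- function(dataset) {
  st <- sufficient_stats(dataset)
  if (st$n_total <= st$n_groups) stop("need N > G for a within covariance", call. = FALSE)
  st$pooled_within_scatter / (st$n_total - st$n_groups)
}

#' Scaled between-cluster sample covariance
#'
#' \eqn{S^*_B = \sum_g n_g(\bar y_g - \bar y)(\bar y_g - \bar y)'/(G-1)}
#' with \eqn{\bar y} the grand mean over all N individuals. Under a balanced
#' design with cluster size n its expectation is \eqn{n\Sigma_B + \Sigma_W};
#' with unequal sizes it is descriptive only and the ML estimator never
#' consumes it.
#'
#' @inheritParams pooled_within_cov
#' @return T x T matrix.
#' @export
between_cov <- function(dataset) {
  y <- .dataset_matrix(dataset)
  cl <- dataset$data$cluster_id
  g <- length(unique(cl))
  if (g < 2L) stop("need at least two clusters", call. = FALSE)
  means <- rowsum(y, cl) / as.vector(table(cl)[as.character(sort(unique(cl)))])
  sizes <- as.vector(table(cl))
  grand <- colMeans(y)
  cen <- sweep(means, 2, grand)
  crossprod(cen * sqrt(sizes)) / (g - 1)
}

#' Sufficient statistics for the two-level likelihood
#'
#' Compresses a clustered dataset into exactly what the ML fit needs: the
#' pooled within-cluster scatter, and per cluster-size class the count of
#' clusters, the mean of their cluster means, and the scatter of cluster
#' means about that mean. The likelihood of any two-level
#' mean-and-covariance structure model is then computable in
#' O(number of size classes) matrix operations.
#'
#' @inheritParams pooled_within_cov
#' @return A `sufficient_stats` list with `n_total`, `n_groups`,
#'   `pooled_within_scatter`, and `size_classes` (list of `size`, `count`,
#'   `mean`, `scatter`).
#' @export
sufficient_stats <- function(dataset) {
  if (inherits(dataset, "sufficient_stats")) return(dataset)
  y <- .dataset_matrix(dataset)
  cl <- dataset$data$cluster_id
  ids <- sort(unique(cl))
  sizes <- as.vector(table(cl)[as.character(ids)])
  if (any(sizes == 0L)) stop("empty cluster", call. = FALSE)
  n_total <- nrow(y)
  g <- length(ids)

  means <- rowsum(y, cl)[as.character(ids), , drop = FALSE] / sizes
  centred <- y - means[match(cl, ids), , drop = FALSE]
  pooled <- crossprod(centred)

  classes <- lapply(sort(unique(sizes)), function(d) {
    md <- means[sizes == d, , drop = FALSE]
    m <- colMeans(md)
    list(size = d, count = nrow(md), mean = m,
         scatter = crossprod(sweep(md, 2, m)))
  })
  structure(
    list(n_total = n_total, n_groups = g,
         pooled_within_scatter = (pooled + t(pooled)) / 2,
         size_classes = classes),
    class = "sufficient_stats"
  )
}

#' Read / write a clustered dataset as CSV
#'
#' Wide layout, one row per individual: `cluster_id, member_id, V1..VT`,
#' comma-separated, `.` decimal, UTF-8. The reader validates the header and
#' rectangularity.
#'
#' @param dataset A `clustered_dataset`.
#' @param path File path.
#' @export
write_dataset_csv <- function(dataset, path) {
  utils::write.csv(dataset$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("cluster_id", "member_id")
  if (!all(need == names(df)[1:2]) || !all(grepl("^V[0-9]+$", names(df)[-(1:2)]))) {
    stop("expected header cluster_id,member_id,V1..VT", call. = FALSE)
  }
  if (anyNA(df)) stop("dataset contains missing values", call. = FALSE)
  structure(list(data = df, condition = NULL, seed = NA_integer_),
            class = "clustered_dataset")
}
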