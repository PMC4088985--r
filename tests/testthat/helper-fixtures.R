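# Shared builders for small in-code fixtures.

# one monthly sample row with defaults
sample_row <- function(site = "s1", dist = "D1", deliv = "S1", year = 1995,
                       month = 1, species = "bromoform", value = 10,
                       below_dl = 0L, dl = 1) {
  data.frame(site_id = site, dist_system_id = dist,
             delivery_system_id = deliv, year = year, month = month,
             species = species, value = value, below_dl = below_dl,
             dl = dl, stringsAsFactors = FALSE)
}

samples_df <- function(...) do.call(rbind, list(...))

# path graph 1-2-3
path3 <- function() adjacency_graph(data.frame(from = c("A1", "A2"),
                                               to = c("A2", "A3")))

# random connected graph on n nodes: random spanning tree + extra edges
random_connected_graph <- function(n, extra = 1) {
  ids <- paste0("g", seq_len(n))
  from <- to <- character(0)
  if (n >= 2) {
    for (k in 2:n) {
      from <- c(from, ids[sample(k - 1, 1)]); to <- c(to, ids[k])
    }
  }
  for (e in seq_len(extra)) {
    ij <- sample(n, 2)
    if (ids[ij[1]] != ids[ij[2]]) {
      from <- c(from, ids[ij[1]]); to <- c(to, ids[ij[2]])
    }
  }
  adjacency_graph(unique(data.frame(from, to)), areas = ids)
}

# brute-force MVN log-density of the ICAR field on the sum-to-zero
# subspace: eigendecomposition of tau * (D - W), positive eigenvalues only
icar_mvn_logdensity <- function(v, graph, tau) {
  n <- length(graph$ids)
  W <- matrix(0, n, n)
  em <- graph$edges
  for (k in seq_len(nrow(em))) {
    W[em[k, 1], em[k, 2]] <- 1
    W[em[k, 2], em[k, 1]] <- 1
  }
  L <- diag(rowSums(W)) - W
  ev <- eigen(tau * L, symmetric = TRUE, only.values = TRUE)$values
  pos <- ev[ev > 1e-9]
  0.5 * sum(log(pos / (2 * pi))) - 0.5 * tau * drop(t(v) %*% L %*% v)
}

# small fast MCMC spec for unit tests
quick_spec <- function(iterations = 1000, ...) {
  model_spec(iterations = iterations, ...)
}

# small simulation config used by several tests
small_config <- function(...) {
  sim_config(n_areas = 16, grid_nrow = 4, grid_ncol = 4, n_hwc = 2,
             n_dist_systems = 10, n_delivery_systems = 4, ...)
}
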