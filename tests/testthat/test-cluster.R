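test_that("neighbour offsets follow the mm radius", {
  expect_equal(nrow(neighbor_offsets(5, 3)), 18L)     # faces + edges
  expect_equal(nrow(neighbor_offsets(3, 3)), 6L)      # faces only
  expect_equal(nrow(neighbor_offsets(5.2, 3)), 26L)   # corners at 5.196 join
  off <- neighbor_offsets(5, 3)
  expect_true(all(sqrt(rowSums((off * 3)^2)) <= 5 + 1e-9))
  expect_false(any(rowSums(abs(off)) == 0))
  expect_error(neighbor_offsets(0, 3), "positive")
})

test_that("cluster labelling respects the neighbourhood", {
  d <- c(6, 6, 6)
  off5 <- neighbor_offsets(5, 3)
  corner <- array(FALSE, d)
  corner[2, 2, 2] <- corner[3, 3, 3] <- TRUE    # pure corner: 5.196 mm apart
  lab <- label_clusters(corner, off5)
  expect_equal(sort(lab$sizes), c(1L, 1L))
  face <- array(FALSE, d)
  face[2, 2, 2] <- face[3, 2, 2] <- TRUE
  expect_equal(label_clusters(face, off5)$sizes, 2L)
  empty <- label_clusters(array(FALSE, d), off5)
  expect_length(empty$sizes, 0L)
})

test_that("labelling matches an igraph component oracle on random fields", {
  skip_if_not_installed("igraph")
  off <- neighbor_offsets(5, 3)
  d <- c(12, 12, 12)
  for (s in 1:3) {
    set.seed(s)
    bin <- array(runif(prod(d)) < 0.3, d)
    lab <- label_clusters(bin, off)
    ## oracle: undirected graph over supra voxels, edges within the offsets
    idx <- which(bin)
    coords <- arrayInd(idx, d)
    id <- seq_along(idx)
    key <- function(m) m[, 1] + d[1] * (m[, 2] - 1) + d[1] * d[2] * (m[, 3] - 1)
    lookup <- integer(prod(d)); lookup[idx] <- id
    edges <- c()
    for (o in seq_len(nrow(off))) {
      nb <- coords + matrix(off[o, ], nrow(coords), 3, byrow = TRUE)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nbk <- key(nb[ok, , drop = FALSE])
      hit <- lookup[nbk] > 0
      edges <- c(edges, rbind(id[ok][hit], lookup[nbk[hit]]))
    }
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    if (length(edges)) g <- igraph::add_edges(g, edges)
    comp <- igraph::components(g)
    expect_equal(sort(lab$sizes), sort(as.integer(comp$csize)))
    ## same partition: labels constant on oracle components
    mine <- lab$labels[idx]
    expect_true(all(tapply(mine, comp$membership, function(v)
      length(unique(v))) == 1))
  }
})

test_that("unsmoothed null fields hit the binomial supra-threshold count", {
  mask <- box_mask(c(10, 10, 10))
  thr <- qnorm(1 - 0.01 / 2)
  set.seed(30)
  counts <- replicate(1000, sum(abs(null_field(mask, 0)) > thr))
  expect_lt(abs(mean(counts) - 10), 1)
})

test_that("the null table is deterministic in the seed", {
  mask <- box_mask(c(8, 8, 8))
  cfg <- alphasim_config(mask, iterations = 120, seed = 42)
  t1 <- simulate_null_max_sizes(cfg)
  t2 <- simulate_null_max_sizes(cfg)
  expect_identical(t1$max_sizes, t2$max_sizes)
  t3 <- simulate_null_max_sizes(alphasim_config(mask, iterations = 120,
                                                seed = 43))
  expect_false(identical(t1$max_sizes, t3$max_sizes))
})

test_that("critical cluster size implements the tail rule", {
  expect_equal(critical_cluster_size(c(1, 1, 1, 2, 9), 0.25), 3L)
  expect_equal(critical_cluster_size(c(1, 1, 1, 2, 9), 1.0), 1L)
  alphas <- c(0.01, 0.05, 0.1, 0.25, 0.5, 1)
  set.seed(31)
  mx <- rpois(500, 4)
  ks <- vapply(alphas, function(a) critical_cluster_size(mx, a), integer(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("smoothing enlarges null clusters: k_crit grows with FWHM", {
  mask <- box_mask(c(12, 12, 10))
  k0 <- critical_cluster_size(simulate_null_max_sizes(
    alphasim_config(mask, fwhm_mm = 0, iterations = 200, seed = 5)), 0.05)
  k6 <- critical_cluster_size(simulate_null_max_sizes(
    alphasim_config(mask, fwhm_mm = 6, iterations = 200, seed = 5)), 0.05)
  expect_gte(k6, k0)
})

test_that("cluster-extent thresholding keeps only large enough clusters", {
  d <- c(14, 14, 10)
  geom <- box_mask(d)
  tvals <- array(0, d)
  tvals[2, 2, 2] <- 8                      # isolated voxel
  tvals[5:9, 5:10, 4:5] <- 7               # 5x6x2 = 60-voxel block
  tvals[7, 7, 4] <- 9                      # its peak
  sm <- structure(list(t = as.numeric(tvals), df = 60,
                       p = 2 * pt(-abs(as.numeric(tvals)), 60),
                       flagged = rep(FALSE, prod(d)),
                       voxel_idx = seq_len(prod(d)), geometry = geom,
                       contrast = "test"), class = "stat_map")
  rep20 <- apply_cluster_threshold(sm, voxel_p = 0.01, k_crit = 20)
  surv <- rep20$clusters[rep20$clusters$survives, ]
  expect_equal(nrow(surv), 1L)
  expect_equal(surv$size, 60L)
  expect_equal(surv$peak_t, 9)
  expect_equal(c(surv$x_mm, surv$y_mm, surv$z_mm),
               as.numeric(voxel_to_mm(c(7, 7, 4), geom)))
  expect_false(rep20$clusters$survives[rep20$clusters$size == 1])

  ## k_crit = 1 reduces to uncorrected voxel thresholding
  rep1 <- apply_cluster_threshold(sm, voxel_p = 0.01, k_crit = 1)
  thr <- qt(1 - 0.01 / 2, 60)
  expect_identical(rep1$survivor_mask$data, array(tvals > thr, d))
})
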