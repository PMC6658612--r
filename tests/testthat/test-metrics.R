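test_that("eigenvector centrality on reference graphs", {
  # complete graph: symmetry forces equal entries at unit norm
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  ec <- eigenvector_centrality(K4)
  expect_equal(unname(ec$centrality), rep(0.5, 4), tolerance = 1e-12)

  # 3-node path: closed-form eigendecomposition
  P3 <- matrix(0, 3, 3)
  P3[1, 2] <- P3[2, 1] <- P3[2, 3] <- P3[3, 2] <- 1
  ec3 <- eigenvector_centrality(P3)
  expect_equal(ec3$eigenvalue, sqrt(2), tolerance = 1e-12)
  expect_equal(unname(ec3$centrality), c(0.5, sqrt(2) / 2, 0.5),
               tolerance = 1e-12)

  expect_error(eigenvector_centrality(matrix(1:9, 3)), "symmetric")
  expect_error(eigenvector_centrality(matrix(c(0, Inf, Inf, 0), 2)),
               "finite")
})

test_that("EC matches a dense eigensolve oracle on signed matrices", {
  set.seed(21)
  for (n in c(3, 6, 10)) {
    M <- rsym(n)
    if (n == 3) {  # the signed triangle case
      M <- matrix(0, 3, 3)
      M[1, 2] <- M[2, 1] <- 0.8
      M[2, 3] <- M[3, 2] <- 0.8
      M[1, 3] <- M[3, 1] <- -0.8
    }
    ec <- eigenvector_centrality(M)
    eig <- eigen(M, symmetric = TRUE)
    k <- which.max(abs(eig$values))
    v <- eig$vectors[, k]
    expect_equal(unname(ec$centrality), abs(v / sqrt(sum(v^2))),
                 tolerance = 1e-10)
    expect_equal(ec$eigenvalue, eig$values[k], tolerance = 1e-10)
  }
})

test_that("EC invariances: positive scaling and Perron-Frobenius", {
  set.seed(22)
  M <- rsym(8)
  expect_equal(eigenvector_centrality(M)$centrality,
               eigenvector_centrality(3.7 * M)$centrality,
               tolerance = 1e-10)
  # nonnegative connected matrix: power iteration agreement
  A <- abs(rsym(7)) + 0.01; diag(A) <- 0
  v <- rep(1 / sqrt(7), 7)
  for (i in 1:500) { v <- A %*% v; v <- v / sqrt(sum(v^2)) }
  expect_equal(unname(eigenvector_centrality(A)$centrality),
               as.numeric(abs(v)), tolerance = 1e-8)
})

test_that("signed clustering coefficient on reference graphs", {
  # positive clique: CC equals the common edge weight
  tri <- matrix(0.5, 3, 3); diag(tri) <- 0
  expect_equal(unname(clustering_coefficient_signed(tri)), rep(0.5, 3),
               tolerance = 1e-12)
  K5 <- matrix(0.3, 5, 5); diag(K5) <- 0
  expect_equal(unname(clustering_coefficient_signed(K5)), rep(0.3, 5),
               tolerance = 1e-12)

  # star graph: no closed triangles
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- c(0.9, -0.4, 0.7)
  expect_equal(unname(clustering_coefficient_signed(star)), rep(0, 4))

  expect_error(clustering_coefficient_signed(diag(3)), "zero diagonal")
})

test_that("CC matches the brute-force triple loop on random matrices", {
  set.seed(23)
  for (rep in 1:5) {
    M <- rsym(6)
    cc <- clustering_coefficient_signed(M)
    oracle <- sapply(1:6, function(i) {
      num <- den <- 0
      for (j in 1:6) for (q in 1:6) {
        if (j == q || j == i || q == i) next
        num <- num + M[i, j] * M[i, q] * M[j, q]
        den <- den + abs(M[i, j] * M[i, q])
      }
      if (den > 0) num / den else 0
    })
    expect_equal(unname(cc), oracle, tolerance = 1e-12)
    expect_true(all(cc >= -1 - 1e-12 & cc <= 1 + 1e-12))
    # sign antisymmetry: flipping every edge negates CC
    expect_equal(unname(clustering_coefficient_signed(-M)), -unname(cc),
                 tolerance = 1e-12)
  }
})

test_that("metric table has full cardinality and relabeling equivariance", {
  set.seed(24)
  n <- 9
  mats <- list()
  subjects <- data.frame(subject_id = c("A", "B"),
                         visit1_condition = c("OXY", "PBO"),
                         visit2_condition = c("PBO", "OXY"),
                         stringsAsFactors = FALSE)
  for (id in subjects$subject_id) for (v in 1:2)
    mats[[paste0(id, "_v", v)]] <- rsym(n)
  tab <- compute_metric_table(mats, subjects)
  expect_equal(nrow(tab), 2 * 2 * n * 2)  # subjects x conditions x nodes x metrics
  expect_equal(sort(unique(tab$condition)), c("OXY", "PBO"))
  expect_false(any(is.na(tab$value)))

  # permuting node order permutes outputs identically
  perm <- sample(n)
  mats_p <- lapply(mats, function(m) m[perm, perm])
  tab_p <- compute_metric_table(mats_p, subjects)
  key <- function(d) d[order(d$subject_id, d$condition, d$metric, d$node_id), ]
  expect_equal(key(tab)$value, key(tab_p)$value, tolerance = 1e-12)

  # ROI restriction selects rows of the full-graph table (no recomputation
  # on the subgraph)
  roi_ids <- rownames(mats[[1]])[1:3]
  sub_tab <- tab[tab$node_id %in% roi_ids & tab$subject_id == "A" &
                   tab$condition == subjects$visit1_condition[1] &
                   tab$metric == "ec", ]
  full_ec <- eigenvector_centrality(mats[["A_v1"]])$centrality
  expect_equal(sub_tab$value[match(roi_ids, sub_tab$node_id)],
               unname(full_ec[roi_ids]))
  sub_ec <- eigenvector_centrality(mats[["A_v1"]][roi_ids, roi_ids])$centrality
  expect_false(isTRUE(all.equal(unname(full_ec[roi_ids]), unname(sub_ec))))

  # a subject with a missing visit is excluded
  expect_message(tab2 <- compute_metric_table(mats[-1], subjects),
                 "missing visit")
  expect_equal(unique(tab2$subject_id), "B")
})
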