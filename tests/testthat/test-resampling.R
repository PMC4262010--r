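test_that("event expansion enumerates each cell with its multiplicity", {
  ev <- expand_events(net_specialised())
  expect_equal(nrow(ev), 4)
  expect_equal(ev$host, c("h1", "h1", "h2", "h2"))
  expect_equal(ev$parasitoid, c("p1", "p1", "p2", "p2"))
  expect_equal(nrow(expand_events(quantweb_network(matrix(1, 1, 1)))), 1)
  expect_error(expand_events(quantweb_network(matrix(c(0.5, 0.5), 1, 2))),
               class = "quantweb_not_applicable_error")
})

test_that("subsampling at n = m reproduces the original network exactly", {
  for (seed in 1:5) {
    net <- random_int_net(5, 4, 80, seed)
    sub <- subsample(net, matrix_size(net), seed = seed * 13)
    expect_identical(sub$a, net$a)
  }
})

test_that("subsamples conserve their event count and never exceed cells", {
  for (k in 1:50) {
    net <- random_int_net(4, 4, 30 + k, k)
    n <- sample(2:matrix_size(net), 1)
    sub <- subsample(net, n, seed = k)
    expect_equal(sum(sub$a), n)
    expect_true(all(sub$a <= net$a[, colnames(sub$a)] + 1e-12))
    expect_identical(rownames(sub$a), rownames(net$a))  # roster retained
    expect_true(all(colSums(sub$a) > 0))                # empty parasitoids drop
  }
  net <- net_specialised()
  expect_error(subsample(net, 0), class = "quantweb_validation_error")
  expect_error(subsample(net, 5), class = "quantweb_validation_error")
})

test_that("single-event draws follow the cell probabilities", {
  a <- matrix(c(3, 0, 0, 1), 2, 2, byrow = TRUE)
  net <- quantweb_network(a)
  hits <- withr::with_seed(99, {
    vapply(seq_len(10000), function(i) {
      sub <- quantweb:::.subsample_counts(net$a, 1L)
      sub[1, 1] == 1
    }, TRUE)
  })
  expect_equal(mean(hits), 0.75, tolerance = 0.027)
})

test_that("subsampling is reproducible from its seed", {
  net <- random_int_net(5, 5, 120, 3)
  expect_identical(subsample(net, 37, seed = 5)$a, subsample(net, 37, seed = 5)$a)
  curves <- rarefaction_curve(net, sizes = c(5, 20), reps = 10, seed = 2)
  curves2 <- rarefaction_curve(net, sizes = c(5, 20), reps = 10, seed = 2)
  expect_identical(curves$mean, curves2$mean)
})

test_that("rarefaction endpoint equals the original metrics exactly", {
  net <- random_int_net(5, 4, 70, 8)
  cur <- rarefaction_curve(net, sizes = matrix_size(net), reps = 3, seed = 1,
                           hosts = "roster")
  full <- compute_all_metrics(net)
  for (metric in c("linkage_density", "connectance", "generality",
                   "vulnerability", "h2prime")) {
    expect_equal(cur$mean[cur$metric == metric], full[[metric]],
                 tolerance = 1e-12, label = metric)
  }
})

test_that("two-event rarefaction of the uniform web matches enumeration", {
  # all C(4,2)=6 two-event subsets of [[1,1],[1,1]], averaged by hand
  net <- net_uniform()
  combos <- utils::combn(4, 2)
  cells <- expand.grid(i = 1:2, j = 1:2)
  oracle <- mean(apply(combos, 2, function(ix) {
    a <- matrix(0, 2, 2, dimnames = dimnames(net$a))
    for (e in ix) a[cells$i[e], cells$j[e]] <- a[cells$i[e], cells$j[e]] + 1
    a <- a[, colSums(a) > 0, drop = FALSE]
    generality(quantweb:::fast_net(net, a))
  }))
  cur <- rarefaction_curve(net, sizes = 2, reps = 400, seed = 4)
  got <- cur$mean[cur$metric == "generality"]
  expect_gte(got, 1)
  expect_lte(got, 2)
  expect_equal(got, oracle, tolerance = 0.1)
})

test_that("the empirical tercile uses the interpolated distribution quantile", {
  mk <- function(sizes) {
    quantweb_collection(purrr::imap(sizes, function(m, i) {
      quantweb_network(matrix(as.double(m), 1, 1), network_id = paste0("n", i),
                       study_id = "s1")
    }))
  }
  expect_equal(empirical_tercile(mk(c(30, 65, 200))), 65)
  expect_equal(empirical_tercile(mk(c(7, 7, 7, 7))), 7)
  expect_equal(empirical_tercile(mk(1:300)), 200, tolerance = 0.01)
  expect_error(empirical_tercile(mk(c(3, 4))), class = "quantweb_validation_error")
})

test_that("standardisation excludes small webs and is exact at the target", {
  nets <- list(
    random_int_net(4, 4, 64, 1),
    random_int_net(4, 4, 65, 2),
    random_int_net(5, 4, 200, 3))
  nets[[1]]$network_id <- "small"; nets[[1]]$study_id <- "s1"
  nets[[2]]$network_id <- "exact"; nets[[2]]$study_id <- "s1"
  nets[[3]]$network_id <- "large"; nets[[3]]$study_id <- "s2"
  coll <- quantweb_collection(nets)
  std <- standardise_collection(coll, std_size = 65, reps = 5, seed = 1)
  excluded <- attr(std, "excluded")
  expect_equal(excluded$network_id, "small")
  expect_match(excluded$reason, "m < 65")
  expect_setequal(std$network_id, c("exact", "large"))
  own <- compute_all_metrics(nets[[2]])
  expect_equal(std$generality[std$network_id == "exact"], own$generality,
               tolerance = 1e-12)
  expect_equal(std$m_original[std$network_id == "large"], 200)
  expect_equal(formals(standardise_collection)$std_size, 65L)
  expect_error(standardise_collection(coll, std_size = 300),
               class = "quantweb_pipeline_error")
})
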