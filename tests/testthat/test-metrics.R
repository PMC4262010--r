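# expected values: hand computations / exhaustive enumeration, frozen.
# For [[2,1],[0,1]]: column 2 is uniform over two hosts so G = 0.5*1 +
# 0.5*2 = 1.5; row 1 has entropy H(2/3,1/3) so V = 0.75*exp(H) + 0.25.

test_that("effective-number metrics match the closed-form toy values", {
  cases <- list(
    list(net = net_specialised(), G = 1, V = 1, LD = 1, Cw = 0.25),
    list(net = net_uniform(), G = 2, V = 2, LD = 2, Cw = 0.5),
    list(net = net_mixed(), G = 1.5, V = 1.6674, LD = 1.5837, Cw = 0.3959))
  for (cs in cases) {
    expect_equal(generality(cs$net), cs$G, tolerance = 1e-4)
    expect_equal(vulnerability(cs$net), cs$V, tolerance = 1e-4)
    expect_equal(linkage_density(cs$net), cs$LD, tolerance = 1e-4)
    expect_equal(weighted_connectance(cs$net), cs$Cw, tolerance = 1e-4)
  }
})

test_that("unparasitised hosts enter S but not the entropies", {
  a <- rbind(mat_specialised, h3 = c(0, 0))
  net <- quantweb_network(a)
  expect_equal(linkage_density(net), 1)
  expect_equal(weighted_connectance(net), 0.2)
  expect_equal(vulnerability(net), 1)
})

test_that("observed entropy follows p log p over positive cells", {
  expect_equal(h2_observed(net_specialised()), log(2), tolerance = 1e-10)
  expect_equal(h2_observed(net_uniform()), log(4), tolerance = 1e-10)
  expect_equal(h2_observed(net_mixed()),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)), tolerance = 1e-10)
})

test_that("entropy bounds match exhaustive enumeration on small marginals", {
  # frozen expectations from the enumeration oracle
  ex <- h2_bounds_exact(c(2, 2), c(2, 2))
  expect_equal(ex$h2_min, log(2), tolerance = 1e-10)
  expect_equal(ex$h2_max, log(4), tolerance = 1e-10)
  ex <- h2_bounds_exact(c(3, 1), c(3, 1))
  expect_equal(ex$h2_min, -(0.75 * log(0.75) + 0.25 * log(0.25)),
               tolerance = 1e-6)

  b <- h2_bounds(net_specialised())
  expect_equal(b$h2_min, log(2), tolerance = 1e-10)
  expect_equal(b$h2_max, log(4), tolerance = 1e-10)

  b <- h2_bounds(net_single())
  expect_equal(b$h2_min, 0)
  expect_equal(b$h2_max, 0)

  # random small marginals: heuristic within 0.02 of the truth in H2' units
  for (seed in 1:10) {
    net <- random_int_net(3, 3, 9, seed)
    a <- net$a
    r <- rowSums(a); c <- colSums(a)
    ex <- h2_bounds_exact(r[r > 0], c[c > 0])
    hb <- h2_bounds(net)
    expect_lte(hb$h2_min - ex$h2_min, 0.05)
    expect_lte(ex$h2_max - hb$h2_max, 0.05)
    expect_gte(hb$h2_min, ex$h2_min - 1e-9)
    expect_lte(hb$h2_max, ex$h2_max + 1e-9)
  }
})

test_that("H2' spans its toy extremes and degenerate cases return 0", {
  expect_equal(h2_prime(net_specialised()), 1)
  expect_equal(h2_prime(net_uniform()), 0)
  expect_equal(h2_prime(net_single()), 0)
  expect_error(h2_prime(quantweb_network(matrix(c(0.5, 0.5), 1, 2))),
               class = "quantweb_not_applicable_error")
})

test_that("identities LD = (G+V)/2 and Cw = LD/S hold on random networks", {
  for (seed in 1:8) {
    net <- random_int_net(5, 4, 60, seed)
    expect_equal(linkage_density(net),
                 (generality(net) + vulnerability(net)) / 2, tolerance = 1e-12)
    expect_equal(weighted_connectance(net), linkage_density(net) / 9,
                 tolerance = 1e-12)
    expect_lte(generality(net), exp(shannon_nats(rowSums(net$a))) + 1e-9)
    expect_lte(vulnerability(net), exp(shannon_nats(colSums(net$a))) + 1e-9)
  }
})

test_that("metrics are invariant to permutation and weight scaling", {
  for (seed in 1:5) {
    net <- random_int_net(5, 4, 50, seed)
    perm <- quantweb_network(net$a[sample(5), sample(4)])
    for (f in list(generality, vulnerability, linkage_density,
                   weighted_connectance, h2_prime)) {
      expect_equal(f(perm), f(net), tolerance = 1e-10)
    }
    # positive non-integer rescaling leaves the Shannon metrics unchanged
    scaled <- quantweb_network(net$a * 2.5)
    expect_equal(generality(scaled), generality(net), tolerance = 1e-10)
    expect_equal(vulnerability(scaled), vulnerability(net), tolerance = 1e-10)
    # integer rescaling leaves H2' almost unchanged (the entropy bounds
    # live on a finer integer lattice, so exact equality is not expected)
    tripled <- quantweb_network(net$a * 3)
    expect_lt(abs(h2_prime(tripled) - h2_prime(net)), 0.05)
  }
})

test_that("compute_all_metrics assembles the vector and flags non-integer H2'", {
  row <- compute_all_metrics(net_specialised())
  expect_equal(row$linkage_density, 1)
  expect_equal(row$connectance, 0.25)
  expect_equal(row$h2prime, 1)
  expect_true(is.na(row$modularity))
  row <- compute_all_metrics(net_uniform(), include_modularity = TRUE)
  expect_equal(row$h2prime, 0)
  expect_equal(row$modularity, 0, tolerance = 1e-9)
  nonint <- quantweb_network(matrix(c(0.5, 1, 0.5, 1), 2, 2))
  row <- compute_all_metrics(nonint)
  expect_true(is.na(row$h2prime))
  expect_false(is.na(row$generality))
})
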