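test_that("taxonomic distances use equal steps scaled to 100", {
  w <- taxonomic_distances(toy_taxonomy())
  expect_equal(w["h1", "h2"], 50)  # congeners: one step of two
  expect_equal(w["h1", "h3"], 100) # different genus: both steps
  expect_equal(diag(w), c(h1 = 0, h2 = 0, h3 = 0))
  # conspecific hosts sit at distance zero
  tax <- taxonomy_table(data.frame(
    host = c("h1", "h2"), species = c("s1", "s1"),
    genus = c("gA", "gA"), family = c("fF", "fF")))
  expect_equal(taxonomic_distances(tax)["h1", "h2"], 0)
})

test_that("distances agree with the vegan equal-step implementation", {
  withr::with_seed(7, {
    n <- 12
    genus <- sample(paste0("g", 1:5), n, replace = TRUE)
    family <- setNames(sample(paste0("f", 1:2), 5, replace = TRUE),
                       paste0("g", 1:5))[genus]
    df <- data.frame(host = paste0("h", 1:n),
                     species = paste0("s", 1:n),
                     genus = genus, family = unname(family))
  })
  w <- taxonomic_distances(taxonomy_table(df))
  cl <- data.frame(genus = df$genus, family = df$family,
                   row.names = df$host)
  wv <- as.matrix(vegan::taxa2dist(cl, varstep = FALSE))
  expect_equal(unname(w[rownames(wv), colnames(wv)]), unname(wv),
               tolerance = 1e-10)
})

test_that("Delta matches hand-computed toy values", {
  # three singleton hosts: pairs at 50, 100, 100 -> 250/3
  a <- matrix(c(1, 1, 1), 3, 1, dimnames = list(c("h1", "h2", "h3"), "p1"))
  net <- quantweb_network(a)
  d <- delta_diversity(net, toy_taxonomy())
  expect_equal(d$delta, 250 / 3, tolerance = 1e-10)
  expect_equal(d$total_abundance, 3)

  # all hosts conspecific -> 0
  tax0 <- taxonomy_table(data.frame(
    host = c("h1", "h2", "h3"), species = "s1", genus = "gA", family = "fF"))
  expect_equal(delta_diversity(net, tax0)$delta, 0)

  # one maximally distant pair -> 100
  a2 <- matrix(c(1, 1), 2, 1, dimnames = list(c("h1", "h3"), "p1"))
  expect_equal(delta_diversity(quantweb_network(a2), toy_taxonomy())$delta, 100)

  # abundance-weighted Delta agrees with vegan::taxondive
  a3 <- matrix(c(3, 1, 0, 0, 2, 1), 3, 2,
               dimnames = list(c("h1", "h2", "h3"), c("p1", "p2")))
  net3 <- quantweb_network(a3)
  d3 <- delta_diversity(net3, toy_taxonomy())
  cl <- data.frame(genus = c("gA", "gA", "gB"), family = "fF",
                   row.names = c("h1", "h2", "h3"))
  comm <- matrix(rowSums(a3), 1, dimnames = list("n", rownames(a3)))
  dv <- vegan::taxondive(comm, vegan::taxa2dist(cl, varstep = FALSE))
  expect_equal(d3$delta, unname(dv$D), tolerance = 1e-10)
})

test_that("Delta is invariant in presence mode and stable in abundance mode", {
  net <- random_int_net(6, 4, 200, 11)
  rownames(net$a) <- paste0("h", 1:6)
  tax <- taxonomy_table(data.frame(
    host = paste0("h", 1:6), species = paste0("s", 1:6),
    genus = c("gA", "gA", "gB", "gB", "gC", "gC"),
    family = c("fF", "fF", "fG", "fG", "fH", "fH")))
  d1 <- delta_diversity(net, tax, abundance = "presence")$delta
  scaled <- quantweb_network(net$a * 7)
  rownames(scaled$a) <- rownames(net$a)
  expect_identical(delta_diversity(scaled, tax, abundance = "presence")$delta, d1)
  # abundance mode: scaling all counts changes Delta only via N(N-1)
  da <- delta_diversity(net, tax)$delta
  da7 <- delta_diversity(scaled, tax)$delta
  expect_lt(abs(da7 - da) / da, 0.01)
})

test_that("adding a conspecific individual cannot raise Delta at the anchor", {
  tax <- toy_taxonomy()
  a2 <- matrix(c(1, 1), 2, 1, dimnames = list(c("h1", "h3"), "p1"))
  base <- delta_diversity(quantweb_network(a2), tax)$delta
  # a second individual of h1 (weight 2 instead of 1)
  a3 <- matrix(c(2, 1), 2, 1, dimnames = list(c("h1", "h3"), "p1"))
  more <- delta_diversity(quantweb_network(a3), tax)$delta
  expect_lte(more, base)
})

test_that("taxonomy validation catches inconsistent nesting and gaps", {
  expect_error(taxonomy_table(data.frame(
    host = c("h1", "h2"), species = c("s1", "s2"),
    genus = c("gA", "gA"), family = c("fF", "fG"))),
    "inconsistent", class = "quantweb_validation_error")
  net <- quantweb_network(matrix(c(1, 1), 2, 1,
                                 dimnames = list(c("h1", "hX"), "p1")))
  expect_error(delta_diversity(net, toy_taxonomy()),
               "not classified", class = "quantweb_validation_error")
  single <- quantweb_network(matrix(1, 1, 1, dimnames = list("h1", "p1")))
  expect_error(delta_diversity(single, toy_taxonomy()),
               class = "quantweb_not_applicable_error")
})
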