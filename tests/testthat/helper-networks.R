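# shared fixtures: the small webs used across the metric tests, and a
# generator of random valid integer networks for property-style checks

mat_specialised <- matrix(c(2, 0, 0, 2), 2, 2, byrow = TRUE,
                          dimnames = list(c("h1", "h2"), c("p1", "p2")))
mat_uniform <- matrix(1, 2, 2, dimnames = list(c("h1", "h2"), c("p1", "p2")))
mat_mixed <- matrix(c(2, 1, 0, 1), 2, 2, byrow = TRUE,
                    dimnames = list(c("h1", "h2"), c("p1", "p2")))
mat_single <- matrix(5, 1, 1, dimnames = list("h1", "p1"))

net_specialised <- function() quantweb_network(mat_specialised)
net_uniform <- function() quantweb_network(mat_uniform)
net_mixed <- function() quantweb_network(mat_mixed)
net_single <- function() quantweb_network(mat_single)

# random integer network with positive column sums
random_int_net <- function(R, C, m, seed) {
  withr::with_seed(seed, {
    repeat {
      p <- matrix(rgamma(R * C, 0.7), R, C)
      a <- matrix(as.double(rmultinom(1, m, as.vector(p / sum(p)))), R, C)
      if (all(colSums(a) > 0)) break
    }
    quantweb_network(a, network_id = paste0("rnd", seed))
  })
}

toy_taxonomy <- function() {
  taxonomy_table(data.frame(
    host = c("h1", "h2", "h3"),
    species = c("s1", "s2", "s3"),
    genus = c("gA", "gA", "gB"),
    family = c("fF", "fF", "fF"),
    stringsAsFactors = FALSE))
}
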