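# Shared fixtures, built in code.

tree_text <- function(txt) pvrpart::validate_tree(ape::read.tree(text = txt))

balanced4 <- function() tree_text("((A:1,B:1):1,(C:1,D:1):1);")

star_tree <- function(n, depth = 2) {
  txt <- paste0("(", paste(sprintf("t%d:%g", seq_len(n), depth), collapse = ","), ");")
  tree_text(txt)
}

random_ultrametric <- function(n, seed, depth = 100) {
  set.seed(seed)
  t <- ape::rphylo(n, birth = 1, death = 0)
  t$edge.length <- t$edge.length * depth / max(ape::node.depth.edgelength(t))
  t
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "pvrpart", mustWork = TRUE)
}

## Small analysis-ready synthetic dataset for pipeline-level tests.
small_dataset <- function(seed = 7, n_species = 60, n_sites = 15, ...) {
  simulate_sla_dataset(n_species = n_species, n_sites = n_sites, seed = seed, ...)
}
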