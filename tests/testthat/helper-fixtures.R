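# Shared fixtures, built lazily and cached for the whole test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

small_map <- function(n_chrom = 3, markers = 20) {
  genome_map(n_chrom, 100, markers)
}

# A mid-size connected panel with phenotypes, reused across test files.
study_fixture <- function() {
  fixture("study", function() {
    arch <- study_architecture(n_qtl = 40)
    sim <- simulate_study(genome_map(7, 100, 30), arch = arch, seed = 101)
    fm <- filter_markers(sim$geno, 1, 0.05)
    list(sim = sim, geno = fm$geno, arch = arch)
  })
}

# Deterministic tiny RCB dataset: 3 lines x 2 blocks, one environment.
hand_plots <- function() {
  data.frame(
    line = rep(c("l1", "l2", "l3"), each = 2),
    population = "p",
    environment = "E1",
    block = rep(1:2, 3),
    trait = "t",
    value = c(11, 9, 11, 13, 15, 13),
    stringsAsFactors = FALSE
  )
}

# Balanced multi-environment plot data simulated from known components.
balanced_plots <- function(L = 40, e = 3, n = 3, sg2 = 1, sge2 = 0.5,
                           se2 = 0.8, seed = 1) {
  set.seed(seed)
  g <- rnorm(L, 0, sqrt(sg2))
  d <- matrix(rnorm(L * e, 0, sqrt(sge2)), L, e)
  env_eff <- seq_len(e)
  out <- expand.grid(line = sprintf("l%02d", seq_len(L)),
                     environment = paste0("E", seq_len(e)),
                     block = seq_len(n), stringsAsFactors = FALSE)
  li <- as.integer(sub("l", "", out$line))
  ei <- as.integer(sub("E", "", out$environment))
  out$population <- "p"
  out$trait <- "t"
  out$value <- 10 + env_eff[ei] + g[li] + d[cbind(li, ei)] +
    rnorm(nrow(out), 0, sqrt(se2))
  out
}
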