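# Shared simulated datasets, built once per test run.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

sim_mir <- function() fixture("sim_mir", function() {
  simulate_experiment(default_config("mir_like", seed = 42))
})

sim_pse <- function() fixture("sim_pse", function() {
  simulate_experiment(default_config("pse_like", seed = 42))
})

sim_mel <- function() fixture("sim_mel", function() {
  simulate_experiment(default_config("mel_like", seed = 42))
})

# small config for fast repeated simulations
small_config <- function(profile = "pse_like", seed = 1) {
  cfg <- default_config(profile, seed = seed)
  cfg$n_genes_per_chromosome <- switch(profile,
    mel_like = c(Chr2 = 80L, Chr4 = 10L, XL = 100L),
    c(Chr2 = 80L, Chr4 = 10L, XL = 60L, XR = 60L, Chr3_neoXY = 60L))
  cfg
}

# a tiny hand-built annotation for unit tests
toy_annotation <- function() {
  gene_annotation(data.frame(
    gene_id = c("a1", "a2", "x1", "x2", "n1"),
    chromosome = c("Chr2", "Chr4", "XL", "XR", "Chr3_neoXY"),
    start = c(0L, 100L, 200L, 300L, 400L),
    end = c(50L, 150L, 250L, 350L, 450L),
    strand = c("+", "-", "+", ".", "-"),
    neoY_orf = c("not_applicable", "not_applicable", "not_applicable",
                 "not_applicable", "intact"),
    n_informative_snps = c(2L, 0L, 3L, 1L, 4L)))
}
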