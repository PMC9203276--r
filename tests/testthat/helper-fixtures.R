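# Shared fixtures. The full-scale pipeline run used by the acceptance tests
# is expensive, so it is computed once per session and memoised.

.fixture_env <- new.env(parent = emptyenv())

small_sim_config <- function(seed = 42, depth = 5000, ...) {
  sim_config(seed = seed, depth = depth, n_promoters = 100, ...)
}

# Study-condition pipeline run: default generator settings (500 promoters,
# 1e5 reads per reference sample) with bedGraph writing off for speed.
acceptance_run <- function() {
  if (is.null(.fixture_env$run)) {
    cfg <- pipeline_config(
      sim = sim_config(seed = 20240101),
      write_tracks = FALSE
    )
    .fixture_env$run <- suppressWarnings(
      run_pipeline(cfg, outdir = file.path(tempdir(), "quantchip_acceptance"))
    )
  }
  .fixture_env$run
}

# Mid-depth run shared by the pipeline-contract tests.
smoke_run <- function() {
  if (is.null(.fixture_env$smoke)) {
    cfg <- pipeline_config(
      sim = sim_config(seed = 7, depth = 5e4),
      write_tracks = TRUE
    )
    .fixture_env$smoke <- list(
      dir = file.path(tempdir(), "quantchip_smoke"),
      res = suppressWarnings(
        run_pipeline(
          pipeline_config(sim = sim_config(seed = 7, depth = 5e4), write_tracks = TRUE),
          outdir = file.path(tempdir(), "quantchip_smoke")
        )
      )
    )
  }
  .fixture_env$smoke
}

# two-group NB count fixture used by the differential-test checks
nb_fixture <- function(n, mu_a, mu_b, disp, seed, n_rep = 3) {
  set.seed(seed)
  m <- cbind(
    matrix(rnbinom(n * n_rep, mu = mu_a, size = 1 / disp), ncol = n_rep),
    matrix(rnbinom(n * n_rep, mu = mu_b, size = 1 / disp), ncol = n_rep)
  )
  rownames(m) <- sprintf("f%04d", seq_len(n))
  colnames(m) <- c(paste0("a", 1:n_rep), paste0("b", 1:n_rep))
  design <- tibble::tibble(
    sample = colnames(m),
    condition = rep(c("A", "B"), each = n_rep)
  )
  list(counts = m, design = design)
}

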