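# Pipeline orchestration, session archive, report rendering, config.

small_inputs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_counts(simulation_design(n_genes = 400,
                                               samples_per_group = 4,
                                               seed = 42))
      cache <<- write_world_inputs(sim)
    }
    cache
  }
})

run_quiet <- function(config) {
  withr::with_options(list(pcalens.verbose = FALSE), run_pipeline(config))
}

test_that("run_pipeline honours optional inputs and names failing stages", {
  inp <- small_inputs()
  st <- run_quiet(list(counts = inp$counts, metadata = inp$metadata,
                       ntop = 200))
  expect_s3_class(st, "session_state")
  expect_false("enrichment" %in% names(st$tables))
  expect_true(all(c("size_factors", "scores_samples", "scree_genes",
                    "sample_distances", "library_sizes") %in% names(st$tables)))

  st_go <- run_quiet(list(counts = inp$counts, metadata = inp$metadata,
                          go = inp$go, ntop = 200))
  expect_true("enrichment" %in% names(st_go$tables))

  expect_error(run_quiet(list(counts = "/nonexistent.tsv",
                              metadata = inp$metadata)),
               "^read_counts")
})

test_that("pipeline runs are byte-reproducible", {
  inp <- small_inputs()
  cfg <- list(counts = inp$counts, metadata = inp$metadata, go = inp$go,
              ntop = 200, seed = 11)
  st1 <- run_quiet(cfg)
  st2 <- run_quiet(cfg)
  for (nm in names(st1$tables)) {
    f1 <- tempfile(); f2 <- tempfile()
    write_table(as.data.frame(st1$tables[[nm]]), f1)
    write_table(as.data.frame(st2$tables[[nm]]), f2)
    expect_identical(readLines(f1), readLines(f2))
  }
})

test_that("session archives round-trip and detect corruption", {
  inp <- small_inputs()
  st <- run_quiet(list(counts = inp$counts, metadata = inp$metadata,
                       go = inp$go, ntop = 150))
  arc <- tempfile(fileext = ".tar")
  save_state(st, arc)
  st2 <- load_state(arc)
  expect_equal(names(st2$tables), names(st$tables))
  for (nm in names(st$tables)) {
    expect_equal(as.data.frame(st2$tables[[nm]]),
                 as.data.frame(st$tables[[nm]]), ignore_attr = TRUE)
  }
  expect_equal(st2$params$ntop, 150)
  expect_identical(st2$version, st$version)

  # tamper: drop one table from the archive
  ex <- tempfile(); dir.create(ex)
  untar(arc, exdir = ex, tar = "internal")
  unlink(file.path(ex, "table_scree_samples.tsv"))
  arc2 <- tempfile(fileext = ".tar")
  old <- setwd(ex); utils::tar(arc2, files = ".", tar = "internal"); setwd(old)
  expect_error(load_state(arc2), "scree_samples")

  # tamper: modify a table so its digest mismatches
  ex3 <- tempfile(); dir.create(ex3)
  untar(arc, exdir = ex3, tar = "internal")
  write(c("x"), file.path(ex3, "table_scree_samples.tsv"), append = TRUE)
  arc3 <- tempfile(fileext = ".tar")
  old <- setwd(ex3); utils::tar(arc3, files = ".", tar = "internal"); setwd(old)
  expect_error(load_state(arc3), "digest mismatch.*scree_samples")

  # newer major version warns
  ex4 <- tempfile(); dir.create(ex4)
  untar(arc, exdir = ex4, tar = "internal")
  mf <- jsonlite::read_json(file.path(ex4, "manifest.json"), simplifyVector = TRUE)
  mf$version <- "99.0.0"
  jsonlite::write_json(mf, file.path(ex4, "manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  # recompute nothing: table digests unchanged
  arc4 <- tempfile(fileext = ".tar")
  old <- setwd(ex4); utils::tar(arc4, files = ".", tar = "internal"); setwd(old)
  expect_warning(load_state(arc4), "newer major version")
})

test_that("reports are deterministic and validate their sections", {
  inp <- small_inputs()
  st <- run_quiet(list(counts = inp$counts, metadata = inp$metadata,
                       go = inp$go, ntop = 150))
  spec <- report_spec(sections = c("overview", "samples_pca", "genes_pca",
                                   "pca2go"))
  h1 <- tempfile(fileext = ".html")
  h2 <- tempfile(fileext = ".html")
  render_report(st, spec, h1)
  render_report(st, spec, h2)
  l1 <- readLines(h1); l2 <- readLines(h2)
  differing <- which(l1 != l2)
  expect_lte(length(differing), 1)
  if (length(differing) == 1) {
    expect_match(l1[differing], "timestamp")
  }
  html <- paste(l1, collapse = "\n")
  for (needle in c("Data overview", "Samples PCA", "Genes PCA",
                   "Functional annotation", "Session parameters",
                   "<svg")) {
    expect_match(html, needle, fixed = TRUE)
  }

  st_min <- run_quiet(list(counts = inp$counts, metadata = inp$metadata,
                           ntop = 150))
  expect_error(render_report(st_min, report_spec(sections = "pca2go"),
                             tempfile()),
               "enrichment")
  expect_error(report_spec(sections = "bogus"), "unknown section")
})

test_that("config files parse as flat key-value text", {
  f <- tempfile()
  writeLines(c("counts: /tmp/c.tsv", "ntop: 250", "scale: TRUE",
               "# a comment", "", "pcs: 1,2,3",
               "multifactor: condition,batch"), f)
  cfg <- read_config(f)
  expect_identical(cfg$counts, "/tmp/c.tsv")
  expect_identical(cfg$ntop, 250L)
  expect_true(cfg$scale)
  expect_equal(cfg$pcs, 1:3)
  expect_equal(cfg$multifactor, c("condition", "batch"))
  writeLines("just some text", f)
  expect_error(read_config(f), "key: value")
})
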