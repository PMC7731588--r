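test_that("the task plan has n, n(n-1)/2 and n tasks per stage", {
  for (n in c(1, 2, 4, 10)) {
    taxa <- sprintf("t%02d", seq_len(n))
    plan <- plan_tasks(taxa)
    counts <- table(plan$stage)
    expect_equal(unname(counts["best_hits"]), n, ignore_attr = TRUE)
    expect_equal(unname(counts["paralogs"]), n, ignore_attr = TRUE)
    expect_equal(if (n >= 2) unname(counts["orthologs"]) else 0L,
                 n * (n - 1) / 2, ignore_attr = TRUE)
    expect_equal(unname(counts["collate"]), 1L, ignore_attr = TRUE)
    expect_equal(unname(counts["cluster"]), 1L, ignore_attr = TRUE)
    # write-disjointness within every stage
    for (st in unique(plan$stage)) {
      outs <- unlist(plan$outputs[plan$stage == st])
      expect_false(anyDuplicated(outs) > 0)
    }
  }
  # plan arithmetic only, no execution: the 2,758-genome decomposition
  big <- plan_tasks(sprintf("g%04d", 1:2758),
                    pipeline_config(include_coorthologs = FALSE),
                    manifests = FALSE)
  expect_equal(sum(big$stage == "orthologs"), 2758 * 2757 / 2)
  expect_error(plan_tasks(c("a", "a")), "duplicate")
  expect_error(plan_tasks(character()), "at least one")
})

test_that("stage inputs are satisfied by prior stages' outputs", {
  plan <- plan_tasks(c("aa", "bb", "cc"))
  stages <- c("best_hits", "orthologs", "paralogs", "coorthologs",
              "collate", "cluster")
  produced <- character()
  for (st in stages) {
    sel <- plan$stage == st
    ins <- unlist(plan$inputs[sel])
    internal <- ins[!grepl("^input/|^gene_lengths", ins)]
    expect_true(all(internal %in% produced),
                info = paste("stage", st))
    produced <- c(produced, unlist(plan$outputs[sel]))
  }
})

test_that("exported task lines are accepted by the CLI parser", {
  plan <- plan_tasks(c("aa", "bb"))
  f <- withr::local_tempfile()
  export_task_list(plan, f)
  lines <- readLines(f)
  expect_equal(length(lines), nrow(plan))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  expect_true(all(lengths(parts) == 3L))
  for (p in parts) {
    argv <- strsplit(p[3], " ", fixed = TRUE)[[1]]
    expect_equal(argv[1], "orthoflow")
    parsed <- parse_cli_args(argv[-1])
    expect_true(parsed$subcommand %in%
                  c("best-hits", "pairs", "collate", "cluster"))
  }
})

run_fixture <- function(dir, seed = 301) {
  simulate_to_dir(dir, n_genomes = 5, n_families = 8,
                  duplication_prob = 0.3, loss_prob = 0.1,
                  background_hit_rate = 0.05, evalue_noise_sd = 2,
                  seed = seed)
}

test_that("pipeline output is byte-identical across parallelism and order", {
  din <- withr::local_tempdir()
  run_fixture(din)
  o1 <- withr::local_tempdir(); o2 <- withr::local_tempdir()
  o3 <- withr::local_tempdir()
  run_pipeline(din, o1, jobs = 1)
  run_pipeline(din, o2, jobs = 4)
  withr::with_seed(8, {
    run_pipeline(din, o3, jobs = 1,
                 task_order = function(idx) sample(idx))
  })
  cs1 <- tree_checksums(o1)
  expect_equal(tree_checksums(o2), cs1)
  expect_equal(tree_checksums(o3), cs1)
  expect_true("groups.txt" %in% names(cs1))
})

test_that("an interrupted run resumes from the ledger without recomputation", {
  din <- withr::local_tempdir()
  run_fixture(din)
  out <- withr::local_tempdir()
  # run only the first two stages, as if the run was killed afterwards
  run_pipeline(din, out, stages = c("best_hits", "orthologs"))
  ledger1 <- readLines(file.path(out, "ledger.tsv"))
  expect_true(any(startsWith(ledger1, "bh:")))
  expect_false(file.exists(file.path(out, "groups.txt")))
  bh_file <- file.path(out, "best_hits", "tx01.tx02.bh.tsv")
  mtime1 <- file.mtime(bh_file)

  res <- run_pipeline(din, out)   # resume
  expect_s3_class(res$groups, "ortho_groups")
  expect_identical(file.mtime(bh_file), mtime1)  # not recomputed
  ledger2 <- readLines(file.path(out, "ledger.tsv"))
  expect_equal(ledger2[seq_along(ledger1)], ledger1)

  # idempotence: a completed pipeline run changes nothing
  cs <- tree_checksums(out)
  run_pipeline(din, out)
  expect_equal(tree_checksums(out), cs)
})

test_that("missing inputs fail pre-flight before any task runs", {
  din <- withr::local_tempdir()
  run_fixture(din)
  file.remove(file.path(din, "tx03.hits.tsv"))
  out <- withr::local_tempdir()
  # taxa still include tx03 (fasta remains) -> named pre-flight error
  expect_error(
    run_pipeline(din, out, taxa = sprintf("tx%02d", 1:5)),
    "tx03.hits.tsv")
  expect_false(dir.exists(file.path(out, "best_hits")))
})

test_that("an ortholog-pair task opens only its two best-hit files", {
  din <- withr::local_tempdir()
  run_fixture(din)
  out <- withr::local_tempdir()
  run_pipeline(din, out, stages = c("best_hits"))

  opened <- character()
  withr::local_options(orthoflow.file_open_hook = function(p) {
    opened <<- c(opened, p)
  })
  orthoflow:::run_ortholog_task("tx01", "tx02", out)
  opened <- basename(opened)
  expect_lte(length(opened), 4L)  # at most 2 best-hit + 2 self files
  bh_opened <- opened[grepl("\\.bh\\.tsv$", opened)]
  expect_lte(length(bh_opened), 2L)
  expect_setequal(bh_opened, c("tx01.tx02.bh.tsv", "tx02.tx01.bh.tsv"))
  expect_true(all(grepl("\\.(bh|self)\\.tsv$", opened)))
})

test_that("pipeline results expose tidy, glance and autoplot views", {
  din <- withr::local_tempdir()
  run_fixture(din, seed = 55)
  out <- withr::local_tempdir()
  res <- run_pipeline(din, out)
  td <- tidy(res)
  expect_true(all(c("group_id", "gene", "taxon") %in% names(td)))
  expect_equal(nrow(td), sum(res$groups$size))
  gl <- glance(res)
  expect_equal(gl$n_taxa_input, 5L)
  expect_gt(gl$n_groups, 0L)
  p <- autoplot(res$groups)
  expect_s3_class(p, "ggplot")
  g <- read_abc(file.path(out, "graph.abc"))
  expect_s3_class(autoplot(g), "ggplot")
})
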