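# Pipeline driver over the sparse file-per-pair layout.
#
# Directory conventions (relative to the run's output directory):
#   best_hits/<A>.<B>.bh.tsv   best hits of genome A against genome B
#   best_hits/<A>.self.tsv     all passing within-genome hits of A
#   pairs/<A>.<B>.ort.tsv      ortholog pairs   (A < B byte order)
#   pairs/<A>.par.tsv          inparalog pairs of A
#   pairs/<A>.<B>.coort.tsv    coortholog pairs (A < B)
#   graph.abc, groups.txt, ledger.tsv, gene_lengths.tsv
#
# Inputs live in one directory: <taxon>.fasta and <taxon>.hits.tsv per
# genome. Every task reads only its manifest inputs and writes only its
# manifest outputs, so tasks within a stage are write-disjoint and can run
# concurrently or be arrayed on a batch system.

bh_path <- function(a, b) file.path("best_hits", paste0(a, ".", b, ".bh.tsv"))
self_path <- function(a) file.path("best_hits", paste0(a, ".self.tsv"))
ort_path <- function(a, b) file.path("pairs", paste0(a, ".", b, ".ort.tsv"))
par_path <- function(a) file.path("pairs", paste0(a, ".par.tsv"))
coort_path <- function(a, b) file.path("pairs", paste0(a, ".", b, ".coort.tsv"))

#' Plan the pipeline's independent tasks
#'
#' Decomposes a run over `n` genomes into stages of mutually independent
#' tasks: one best-hit scan per genome, one ortholog task per unordered
#' genome pair (`n(n-1)/2`), one inparalog task per genome, optionally one
#' coortholog task per pair, then a single collate task and a single
#' clustering task. Tasks within a stage share no output paths, so any of
#' them may run concurrently; each stage only needs the previous stages'
#' outputs. The plan is deterministic: taxa are processed in byte order.
#'
#' @param taxa Character vector of genome codes (>= 1, unique).
#' @param config A [pipeline_config()].
#' @param manifests Attach per-task input/output file manifests (list
#'   columns)? Default TRUE; set FALSE when planning runs over thousands of
#'   genomes, where the quadratic manifest would dwarf the plan itself.
#' @return A tibble with columns `stage`, `task_id`, `inputs` and `outputs`
#'   (list columns of relative paths; `NULL` entries when
#'   `manifests = FALSE`) and `command` (a CLI invocation equivalent to the
#'   task, suitable for batch arrays).
#' @examples
#' dplyr::count(plan_tasks(c("eco", "stm", "sen")), stage)
#' @export
plan_tasks <- function(taxa, config = pipeline_config(), manifests = TRUE) {
  if (length(taxa) < 1) stop("at least one genome required", call. = FALSE)
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon code(s): ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "),
         call. = FALSE)
  }
  taxa <- radix_sort(taxa)
  n <- length(taxa)
  if (n >= 2) {
    idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
    pa <- taxa[idx[, "row"]]
    pb <- taxa[idx[, "col"]]
    ord <- radix_order(pa, pb)
    pa <- pa[ord]; pb <- pb[ord]
  } else {
    pa <- pb <- character()
  }
  # pair two same-length path vectors into a list column cheaply
  zip2 <- function(x, y) {
    if (length(x) == 0) return(list())
    unname(split(c(rbind(x, y)), rep(seq_along(x), each = 2)))
  }
  as_list_col <- function(x) lapply(x, identity)

  stage_tbl <- function(stage, task_id, inputs, outputs, command) {
    tibble::tibble(stage = stage, task_id = task_id,
                   inputs = if (manifests) inputs else
                     vector("list", length(task_id)),
                   outputs = if (manifests) outputs else
                     vector("list", length(task_id)),
                   command = command)
  }

  bh_out <- if (manifests) {
    lapply(taxa, function(a)
      c(bh_path(a, setdiff(taxa, a)), self_path(a)))
  } else NULL
  plan <- list(
    stage_tbl("best_hits", paste0("bh:", taxa),
              if (manifests) zip2(paste0("input/", taxa, ".hits.tsv"),
                                  rep("gene_lengths.tsv", n)) else NULL,
              bh_out,
              paste("orthoflow best-hits --taxon", taxa))
  )
  if (length(pa) > 0) {
    plan[[length(plan) + 1L]] <- stage_tbl(
      "orthologs", paste0("ort:", pa, ".", pb),
      if (manifests) zip2(bh_path(pa, pb), bh_path(pb, pa)) else NULL,
      if (manifests) as_list_col(ort_path(pa, pb)) else NULL,
      paste("orthoflow pairs --stage orthologs --taxon-a", pa,
            "--taxon-b", pb))
  }
  par_in <- if (manifests) {
    lapply(taxa, function(a) {
      others <- setdiff(taxa, a)
      c(self_path(a), bh_path(a, others),
        ort_path(pmin(a, others), pmax(a, others)))
    })
  } else NULL
  plan[[length(plan) + 1L]] <- stage_tbl(
    "paralogs", paste0("par:", taxa), par_in,
    if (manifests) as_list_col(par_path(taxa)) else NULL,
    paste("orthoflow pairs --stage paralogs --taxon", taxa))
  if (config$include_coorthologs && length(pa) > 0) {
    co_in <- if (manifests) {
      unname(split(c(rbind(ort_path(pa, pb), par_path(pa), par_path(pb),
                           bh_path(pa, pb), bh_path(pb, pa))),
                   rep(seq_along(pa), each = 5)))
    } else NULL
    plan[[length(plan) + 1L]] <- stage_tbl(
      "coorthologs", paste0("coort:", pa, ".", pb), co_in,
      if (manifests) as_list_col(coort_path(pa, pb)) else NULL,
      paste("orthoflow pairs --stage coorthologs --taxon-a", pa,
            "--taxon-b", pb))
  }
  all_pair_files <- if (manifests) c(
    if (length(pa) > 0) ort_path(pa, pb),
    par_path(taxa),
    if (config$include_coorthologs && length(pa) > 0) coort_path(pa, pb)
  )
  plan[[length(plan) + 1L]] <- stage_tbl(
    "collate", "collate", if (manifests) list(all_pair_files) else NULL,
    if (manifests) list("graph.abc") else NULL, "orthoflow collate")
  plan[[length(plan) + 1L]] <- stage_tbl(
    "cluster", "cluster", if (manifests) list("graph.abc") else NULL,
    if (manifests) list("groups.txt") else NULL,
    paste("orthoflow cluster --inflation", format(config$mcl_inflation)))
  out <- dplyr::bind_rows(plan)
  attr(out, "taxa") <- taxa
  class(out) <- c("task_plan", class(out))
  out
}

#' Export the task plan as a scheduler-agnostic task list
#'
#' Writes one task per line — `stage<tab>task-id<tab>CLI command` — so any
#' batch system can array over the lines of a stage.
#'
#' @param plan A plan from [plan_tasks()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_task_list <- function(plan, path) {
  writeLines(sprintf("%s\t%s\t%s", plan$stage, plan$task_id, plan$command),
             path)
  invisible(path)
}

# ---- task bodies -----------------------------------------------------------

run_best_hits_task <- function(a, taxa, input_dir, out_dir, lengths, config) {
  hits <- read_hits(file.path(input_dir, paste0(a, ".hits.tsv")),
                    query_taxon = a)
  bh <- find_best_hits(hits, lengths, config, taxon = a)
  dir.create(file.path(out_dir, "best_hits"), showWarnings = FALSE,
             recursive = TRUE)
  for (b in setdiff(taxa, a)) {
    tbl <- bh$between[[b]] %||% empty_best_hit_table(a, b)
    write_best_hits(tbl, file.path(out_dir, bh_path(a, b)))
  }
  write_best_hits(bh$self, file.path(out_dir, self_path(a)))
  invisible(NULL)
}

# honours the memory contract: opens exactly the two best-hit files
run_ortholog_task <- function(a, b, out_dir) {
  ab <- read_best_hits(file.path(out_dir, bh_path(a, b)), a, b)
  ba <- read_best_hits(file.path(out_dir, bh_path(b, a)), b, a)
  pairs <- reciprocal_best_pairs(ab, ba)
  scored <- normalize_ortholog_scores(pairs)
  dir.create(file.path(out_dir, "pairs"), showWarnings = FALSE,
             recursive = TRUE)
  write_scored_pairs(scored, file.path(out_dir, ort_path(a, b)))
  invisible(NULL)
}

run_paralog_task <- function(a, taxa, out_dir, config) {
  others <- setdiff(taxa, a)
  # between-genome levels: one best-hit file in memory at a time
  cutoffs <- stats::setNames(numeric(), character())
  for (b in others) {
    tbl <- read_best_hits(file.path(out_dir, bh_path(a, b)), a, b)
    part <- inter_genome_cutoffs(list(tbl))
    merged <- c(cutoffs, part)
    cutoffs <- tapply(merged, names(merged), max)
    cutoffs <- stats::setNames(as.numeric(cutoffs), names(cutoffs))
  }
  self_tbl <- read_best_hits(file.path(out_dir, self_path(a)), a, a)
  inpar <- find_inparalogs(self_tbl, cutoffs)
  og <- character()
  for (b in others) {
    ort <- read_scored_pairs(
      file.path(out_dir, ort_path(min(a, b), max(a, b))), "ortholog")
    og <- unique(c(og, ort$a[gene_taxon2(ort$a) == a],
                   ort$b[gene_taxon2(ort$b) == a]))
  }
  scored <- normalize_inparalog_scores(inpar, og, config)
  dir.create(file.path(out_dir, "pairs"), showWarnings = FALSE,
             recursive = TRUE)
  write_scored_pairs(scored, file.path(out_dir, par_path(a)))
  invisible(NULL)
}

# taxon prefix without re-validation (hot path on trusted internal files)
gene_taxon2 <- function(x) sub("\\|.*$", "", x)

run_coortholog_task <- function(a, b, out_dir, config) {
  ort <- read_scored_pairs(file.path(out_dir, ort_path(a, b)), "ortholog")
  inpar_a <- read_scored_pairs(file.path(out_dir, par_path(a)), "inparalog")
  inpar_b <- read_scored_pairs(file.path(out_dir, par_path(b)), "inparalog")
  ab <- read_best_hits(file.path(out_dir, bh_path(a, b)), a, b)
  ba <- read_best_hits(file.path(out_dir, bh_path(b, a)), b, a)
  co <- find_coorthologs(ort, inpar_a, inpar_b, ab, ba, config)
  write_scored_pairs(co, file.path(out_dir, coort_path(a, b)))
  invisible(NULL)
}

run_collate_task <- function(plan, out_dir) {
  files <- plan$inputs[plan$task_id == "collate"][[1]]
  pieces <- lapply(files, function(f) {
    cat_from_name <- if (grepl("\\.ort\\.tsv$", f)) "ortholog"
      else if (grepl("\\.par\\.tsv$", f)) "inparalog" else "coortholog"
    read_scored_pairs(file.path(out_dir, f), cat_from_name)
  })
  graph <- build_graph(dplyr::bind_rows(pieces))
  write_abc(graph, file.path(out_dir, "graph.abc"))
  invisible(NULL)
}

run_cluster_task <- function(out_dir, config, mcl_binary = NULL) {
  graph <- read_abc(file.path(out_dir, "graph.abc"))
  res <- if (is.null(mcl_binary)) {
    mcl_cluster(graph, inflation = config$mcl_inflation,
                max_iterations = config$mcl_max_iterations,
                pruning_threshold = config$mcl_pruning_threshold,
                convergence_tol = config$mcl_convergence_tol)
  } else {
    mcl_cluster_external(graph, mcl_binary, inflation = config$mcl_inflation)
  }
  groups <- to_groups(res, prefix = config$group_prefix,
                      start_index = config$group_start_index)
  write_groups(groups, file.path(out_dir, "groups.txt"))
  invisible(NULL)
}

# ---- driver ----------------------------------------------------------------

read_ledger <- function(path) {
  if (!file.exists(path)) return(character())
  readLines(path)
}

append_ledger <- function(path, task_ids) {
  if (length(task_ids)) cat(paste0(task_ids, "\n"), file = path, sep = "",
                            append = TRUE)
}

#' Run the full orthology pipeline over a directory of genomes
#'
#' Executes the planned stages in order — best hits, orthologs, inparalogs,
#' optionally coorthologs, graph collation, Markov clustering — over the
#' input directory's `<taxon>.fasta` / `<taxon>.hits.tsv` files. Tasks
#' within a stage are independent and write disjoint files, so they may run
#' concurrently (`jobs` > 1 fans out with [parallel::mclapply()]) or in any
#' completion order with byte-identical results. A ledger of completed task
#' ids (`ledger.tsv`) makes interrupted runs resumable without recomputing
#' finished tasks.
#'
#' @param input_dir Directory with one `<taxon>.fasta` and one
#'   `<taxon>.hits.tsv` per genome.
#' @param out_dir Output directory (created if needed).
#' @param taxa Genome codes; discovered from `*.hits.tsv` when NULL.
#' @param config A [pipeline_config()].
#' @param jobs Parallel fan-out degree within a stage (default 1).
#' @param stages Stages to execute, in pipeline order; default all. Running
#'   a prefix of the stages and calling again later resumes from the ledger.
#' @param task_order Optional function applied to each stage's pending task
#'   index vector (e.g. `sample`) to permute execution order; output is
#'   unaffected.
#' @param mcl_binary Optional path to an external `mcl` executable used for
#'   the clustering stage instead of the built-in implementation.
#' @return An object of class `"orthoflow_run"`: list with `out_dir`,
#'   `taxa`, `plan`, `groups` (an `"ortho_groups"` tibble) when the cluster
#'   stage ran, and `config`.
#' @export
run_pipeline <- function(input_dir, out_dir, taxa = NULL,
                         config = pipeline_config(), jobs = 1L,
                         stages = c("best_hits", "orthologs", "paralogs",
                                    "coorthologs", "collate", "cluster"),
                         task_order = NULL, mcl_binary = NULL) {
  if (is.null(taxa)) {
    hits_files <- list.files(input_dir, pattern = "\\.hits\\.tsv$")
    taxa <- sub("\\.hits\\.tsv$", "", hits_files)
  }
  plan <- plan_tasks(taxa, config)
  taxa <- attr(plan, "taxa")
  # pre-flight: every genome's inputs must exist before anything runs
  for (a in taxa) {
    for (f in c(paste0(a, ".fasta"), paste0(a, ".hits.tsv"))) {
      if (!file.exists(file.path(input_dir, f))) {
        stop("missing input file: ", file.path(input_dir, f), call. = FALSE)
      }
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lengths_file <- file.path(out_dir, "gene_lengths.tsv")
  if (!file.exists(lengths_file)) {
    proteomes <- lapply(taxa, function(a)
      read_proteome(file.path(input_dir, paste0(a, ".fasta"))))
    len <- gene_lengths(proteomes)
    len <- len[radix_order(names(len))]
    writeLines(sprintf("%s\t%s", names(len), num_c17(len)), lengths_file)
  }
  lv <- read_gene_lengths(lengths_file)

  ledger_file <- file.path(out_dir, "ledger.tsv")
  done <- read_ledger(ledger_file)
  stages <- match.arg(stages, several.ok = TRUE)
  if (!config$include_coorthologs) stages <- setdiff(stages, "coorthologs")

  runner <- function(fns) {
    if (length(fns) == 0) return(invisible(NULL))
    if (jobs > 1 && .Platform$OS.type == "unix") {
      res <- parallel::mclapply(fns, function(f) {
        tryCatch({ f(); NULL }, error = function(e) conditionMessage(e))
      }, mc.cores = jobs)
    } else {
      res <- lapply(fns, function(f) {
        tryCatch({ f(); NULL }, error = function(e) conditionMessage(e))
      })
    }
    errs <- Filter(Negate(is.null), res)
    if (length(errs) > 0) {
      stop("stage aborted; first task error: ", errs[[1]], call. = FALSE)
    }
  }

  for (stage in c("best_hits", "orthologs", "paralogs", "coorthologs",
                  "collate", "cluster")) {
    if (!stage %in% stages) next
    st <- plan[plan$stage == stage, , drop = FALSE]
    pending <- which(!(st$task_id %in% done))
    if (!is.null(task_order) && length(pending) > 1) {
      pending <- task_order(pending)
    }
    fns <- lapply(pending, function(i) {
      id <- st$task_id[i]
      force(id)
      switch(
        stage,
        best_hits = {
          a <- sub("^bh:", "", id)
          function() run_best_hits_task(a, taxa, input_dir, out_dir, lv,
                                        config)
        },
        orthologs = {
          ab <- strsplit(sub("^ort:", "", id), ".", fixed = TRUE)[[1]]
          function() run_ortholog_task(ab[1], ab[2], out_dir)
        },
        paralogs = {
          a <- sub("^par:", "", id)
          function() run_paralog_task(a, taxa, out_dir, config)
        },
        coorthologs = {
          ab <- strsplit(sub("^coort:", "", id), ".", fixed = TRUE)[[1]]
          function() run_coortholog_task(ab[1], ab[2], out_dir, config)
        },
        collate = function() run_collate_task(plan, out_dir),
        cluster = function() run_cluster_task(out_dir, config, mcl_binary)
      )
    })
    runner(fns)
    # ledger rows in plan order regardless of completion order, so the
    # output tree is byte-identical under any schedule
    append_ledger(ledger_file, st$task_id[sort(pending)])
    done <- c(done, st$task_id[pending])
  }

  groups <- if (file.exists(file.path(out_dir, "groups.txt"))) {
    read_groups(file.path(out_dir, "groups.txt"))
  } else NULL
  structure(
    list(out_dir = out_dir, taxa = taxa, plan = plan, groups = groups,
         config = config),
    class = "orthoflow_run"
  )
}

read_gene_lengths <- function(path) {
  notify_file_open(path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- stringr::str_split_fixed(lines, stringr::fixed("\t"), 2L)
  stats::setNames(as.numeric(parts[, 2]), parts[, 1])
}

#' @exportS3Method base::print
print.orthoflow_run <- function(x, ...) {
  cat(sprintf("<orthoflow_run> %d genomes -> %s\n", length(x$taxa),
              x$out_dir))
  if (!is.null(x$groups)) {
    cat(sprintf("  %d ortholog groups over %d genes\n", nrow(x$groups),
                sum(x$groups$size)))
  }
  invisible(x)
}
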