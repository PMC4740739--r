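#' Run the full LGT screen
#'
#' Orchestrates every stage on disk: input acquisition (simulation or
#' files), database masking, whole-scaffold searches, scaffold triage, the
#' windowed scan, junction validation, expression classification and
#' summary reports, finishing with a machine-readable run manifest
#' (parameters, seed, package version, per-stage record counts). Stage
#' timing is logged to stderr; no output file contains a timestamp, so a
#' rerun with the same configuration is byte-identical.
#'
#' @param config Configuration list, a \code{\link{simulation_config}}
#'   (treated as a \code{simulate} block), or a path to a JSON file.
#'   Recognized
#'   blocks, all optional: \code{simulate} (fields of
#'   \code{\link{simulation_config}}) or \code{inputs} (paths:
#'   \code{genome}, \code{bacterial_db}, \code{animal_db}, optional
#'   \code{pairs}, optional named \code{coverage}), \code{mask}
#'   (\code{\link{mask_params}}), \code{scoring}
#'   (\code{\link{scoring_params}}), \code{scan} (\code{\link{scan_params}}),
#'   \code{classify} (\code{min_cov}), \code{junction}
#'   (\code{min_overhang, s, p}), \code{expression} (\code{t0, t1}).
#' @param outdir Output directory (created; stages write into
#'   subdirectories).
#' @return Invisibly, a list with the main stage results (\code{calls},
#'   \code{candidates}, \code{support}, \code{expression},
#'   \code{genus_summary}, \code{manifest}).
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (inherits(config, "simulation_config")) config <- list(simulate = unclass(config))
  stopifnot(is.list(config))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("inputs", "mask", "search", "classify", "scan", "junction",
              "expression", "report"))
    dir.create(file.path(outdir, d), showWarnings = FALSE)

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[lgtscreen] stage %-12s %6.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  take <- function(block, fn) do.call(fn, if (is.null(config[[block]]))
    list() else config[[block]])
  mask_p <- take("mask", mask_params)
  scoring <- take("scoring", scoring_params)
  scan_p <- take("scan", scan_params)
  counts <- list()

  inp <- stage("inputs", {
    if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      if (!is.null(config$seed) && is.null(sim_args$seed))
        sim_args$seed <- config$seed
      cfg <- do.call(simulation_config, sim_args)
      sim <- simulate_screen_inputs(cfg)
      write_scaffolds(sim$genome, file.path(outdir, "inputs", "genome.fa"))
      write_scaffolds(sim$donors, file.path(outdir, "inputs", "bacterial_db.fa"))
      write_scaffolds(sim$animal_db, file.path(outdir, "inputs", "animal_db.fa"))
      .write_tsv(sim$truth$implants, file.path(outdir, "inputs", "truth_implants.tsv"))
      .write_tsv(sim$truth$contaminants,
                 file.path(outdir, "inputs", "truth_contaminants.tsv"))
      write_pair_placements(sim$pairs, file.path(outdir, "inputs", "pairs.tsv"))
      write_bedgraph(sim$coverage$condA, file.path(outdir, "inputs", "condA.bedgraph"))
      write_bedgraph(sim$coverage$condB, file.path(outdir, "inputs", "condB.bedgraph"))
      list(genome = sim$genome, bacterial_db = sim$donors,
           animal_db = sim$animal_db, pairs = sim$pairs,
           coverage = list(condA = sim$coverage$condA,
                           condB = sim$coverage$condB))
    } else if (!is.null(config$inputs)) {
      pth <- config$inputs
      cov <- if (!is.null(pth$coverage))
        lapply(pth$coverage, read_bedgraph) else NULL
      list(genome = read_scaffolds(pth$genome),
           bacterial_db = read_scaffolds(pth$bacterial_db),
           animal_db = read_scaffolds(pth$animal_db),
           pairs = if (!is.null(pth$pairs)) read_pair_placements(pth$pairs)
                   else NULL,
           coverage = cov)
    } else stop("config needs a 'simulate' or an 'inputs' block")
  })
  counts$genome_scaffolds <- length(inp$genome)

  masked <- stage("mask", {
    mk <- mask_scaffolds(inp$bacterial_db, mask_p, mode = "soft")
    write_scaffolds(mk$scaffolds, file.path(outdir, "mask", "bacterial_db.masked.fa"))
    .write_tsv(mk$intervals, file.path(outdir, "mask", "mask_intervals.tsv"))
    mk
  })
  counts$mask_intervals <- nrow(masked$intervals)

  idx <- stage("index", {
    list(bact = build_index(masked$scaffolds, scoring, db_class = "bacterial"),
         animal = build_index(inp$animal_db, scoring, db_class = "animal"))
  })

  hits <- stage("search", {
    bh <- search_scaffolds(inp$genome, idx$bact, scoring)
    ah <- search_scaffolds(inp$genome, idx$animal, scoring)
    write_tabular_hits(bh, file.path(outdir, "search", "scaffold_bacterial_hits.tsv"))
    write_tabular_hits(ah, file.path(outdir, "search", "scaffold_animal_hits.tsv"))
    list(bact = bh, animal = ah)
  })
  counts$scaffold_bacterial_hits <- nrow(hits$bact)
  counts$scaffold_animal_hits <- nrow(hits$animal)

  calls <- stage("classify", {
    cl <- classify_scaffolds(inp$genome, hits$bact, hits$animal,
                             min_cov = config$classify$min_cov %||% 0.5)
    .write_tsv(cl, file.path(outdir, "classify", "scaffold_calls.tsv"))
    .write_tsv(summarize_bacterial_bins(cl),
               file.path(outdir, "classify", "bacterial_bins.tsv"))
    cl
  })
  counts$scaffold_calls <- nrow(calls)
  counts$bacterial_scaffolds <- sum(calls$call == "bacterial")

  candidates <- stage("scan", {
    cd <- run_scan(inp$genome, idx$bact, idx$animal, scan_p, scoring,
                   calls = calls)
    .write_tsv(cd, file.path(outdir, "scan", "candidates.tsv"))
    write_candidates_bed(cd, file.path(outdir, "scan", "candidates.bed"))
    write_candidates_gff3(cd, file.path(outdir, "scan", "candidates.gff3"))
    cd
  })
  counts$candidates <- nrow(candidates)

  support <- stage("junction", {
    if (is.null(inp$pairs)) NULL else {
      jp <- config$junction
      sp <- validate_junctions(candidates, inp$pairs, inp$genome,
                               min_overhang = jp$min_overhang %||% 20L,
                               s = jp$s %||% 1L, p = jp$p %||% 1L)
      .write_tsv(sp, file.path(outdir, "junction", "junction_support.tsv"))
      sp
    }
  })
  if (!is.null(support)) counts$supported_candidates <- sum(support$supported)

  expr <- stage("expression", {
    if (is.null(inp$coverage)) NULL else {
      ep <- config$expression
      ex <- classify_expression(candidates, inp$coverage,
                                t0 = ep$t0 %||% 0.0, t1 = ep$t1 %||% 1.0)
      .write_tsv(ex, file.path(outdir, "expression", "expression_calls.tsv"))
      ex
    }
  })
  if (!is.null(expr)) counts$differential_candidates <- sum(expr$differential)

  gs <- stage("report", {
    g <- summarize_genera(candidates)
    .write_tsv(g, file.path(outdir, "report", "genus_summary.tsv"))
    .write_tsv(length_histogram(candidates, bin = 10L,
                                min_len = scan_p$min_len),
               file.path(outdir, "report", "length_histogram.tsv"))
    ann <- candidates
    if (!is.null(support))
      ann <- merge(ann, support, by = "candidate_id", sort = FALSE)
    if (!is.null(expr))
      ann <- merge(ann, expr, by = "candidate_id", sort = FALSE)
    ann <- ann[order(ann$scaffold, ann$start), , drop = FALSE]
    .write_tsv(ann, file.path(outdir, "report", "candidates_annotated.tsv"))
    g
  })

  manifest <- list(
    tool = "lgtscreen",
    version = as.character(utils::packageVersion("lgtscreen")),
    seed = config$seed %||% config$simulate$seed,
    parameters = list(mask = unclass(mask_p), scoring = unclass(scoring),
                      scan = unclass(scan_p)),
    counts = counts)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(calls = calls, candidates = candidates, support = support,
                 expression = expr, genus_summary = gs, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
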