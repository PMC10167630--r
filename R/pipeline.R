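# pipeline: stage orchestration with config, seeds, logging and multi-sample
# co-analysis. Stage outputs are plain TSV/VCF; a state file lets later
# stages (or stage reruns) reuse earlier results unchanged.

#' Validate and normalize a run configuration
#'
#' @param config A list or path to a YAML file with fields: `samples` (list
#'   of `list(name, sam, mode)`), `genome_fasta`, `targets_bed`,
#'   `adjacent_span`, `out_dir`, `seed`, optional `params` (stage
#'   parameters) and `filters` (passed to [filter_spec()]).
#' @return Normalized `RunConfig` list.
#' @export
run_config <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    stopifnot(!is.null(config$samples), !is.null(config$genome_fasta),
              !is.null(config$targets_bed), !is.null(config$out_dir))
    config$seed <- as.integer(config$seed %||% 1L)
    config$adjacent_span <- as.integer(config$adjacent_span %||% 250000L)
    p <- config$params %||% list()
    config$params <- list(
        mapq_min = as.integer(p$mapq_min %||% 20L),
        allowance = as.integer(p$allowance %||% 1L),
        min_sv_size = as.integer(p$min_sv_size %||% 50L),
        max_proper_insert = if (!is.null(p$max_proper_insert))
            as.integer(p$max_proper_insert) else NULL,
        consensus = p$consensus %||% "candidates",
        threshold = as.numeric(p$threshold %||% 0.667),
        max_depth = as.integer(p$max_depth %||% 11L),
        min_clip = as.integer(p$min_clip %||% 5L),
        total_allowance = as.integer(p$total_allowance %||% 5L),
        min_depth = as.integer(p$min_depth %||% 10L),
        min_allele_fraction = as.numeric(p$min_allele_fraction %||% 0.2),
        iterations = as.integer(p$iterations %||% 10000L))
    for (s in config$samples) {
        if (!file.exists(s$sam)) stop2("sample input not found: ", s$sam)
    }
    if (!file.exists(config$genome_fasta))
        stop2("genome FASTA not found: ", config$genome_fasta)
    if (!file.exists(config$targets_bed))
        stop2("targets BED not found: ", config$targets_bed)
    structure(config, class = "RunConfig")
}

pipeline_stages <- c("collate", "extract", "find", "filter", "genotype",
                     "stats")

#' Run the SV detection pipeline
#'
#' Executes the requested stages in fixed order (collate, extract, find,
#' filter, genotype, stats). Each stage writes TSV/VCF artifacts plus a
#' machine-readable run log to `out_dir`; state is carried between stages
#' (and between invocations via `state.rds` under `out_dir`), so a stage can
#' be rerun with changed parameters while reusing earlier outputs.
#'
#' @param config A `RunConfig` (or list/YAML path accepted by
#'   [run_config()]).
#' @param stages Subset of stages to run.
#' @return Invisibly, the pipeline state (list of stage results).
#' @export
run_pipeline <- function(config, stages = pipeline_stages) {
    cfg <- if (inherits(config, "RunConfig")) config else run_config(config)
    stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
    stages <- pipeline_stages[pipeline_stages %in% stages]
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    state_path <- file.path(cfg$out_dir, "state.rds")
    state <- if (file.exists(state_path)) readRDS(state_path) else list()
    need <- function(what, stage) {
        if (is.null(state[[what]]))
            stop2("stage '", stage, "' requires output of an earlier stage; ",
                  "run '", what, "' first")
        state[[what]]
    }
    genome <- load_genome(cfg$genome_fasta)
    targets <- load_targets(cfg$targets_bed, cfg$adjacent_span, genome)
    p <- cfg$params
    log <- list(seed = cfg$seed, stages = stages, params = p,
                samples = vapply(cfg$samples, `[[`, "", "name"))

    if ("collate" %in% stages) {
        state$collate <- lapply(cfg$samples, function(s) {
            aln <- read_alignments(s$sam, sample = s$name)
            aln <- alignment_groups(aln)
            collate_molecules(aln, mode = s$mode %||% "ligation_duplex",
                              mapq_min = p$mapq_min,
                              allowance = p$allowance)
        })
        names(state$collate) <- vapply(cfg$samples, `[[`, "", "name")
        for (nm in names(state$collate)) {
            data.table::fwrite(state$collate[[nm]]$molecules,
                file.path(cfg$out_dir, paste0("molecules_", nm, ".tsv")),
                sep = "\t")
        }
        log$n_molecules <- vapply(state$collate,
                                  function(x) x$stats$n_molecules, 1)
    }
    if ("extract" %in% stages) {
        coll <- need("collate", "extract")
        state$extract <- lapply(coll, function(cs)
            extract_junctions(cs, max_proper_insert = p$max_proper_insert,
                              min_sv_size = p$min_sv_size,
                              consensus = p$consensus,
                              threshold = p$threshold,
                              max_depth = p$max_depth, seed = cfg$seed))
        for (nm in names(state$extract)) {
            data.table::fwrite(state$extract[[nm]]$candidates,
                file.path(cfg$out_dir, paste0("candidates_", nm, ".tsv")),
                sep = "\t")
        }
    }
    if ("find" %in% stages) {
        ex <- need("extract", "find")
        res <- find_svs(ex, genome, targets,
                        max_proper_insert = p$max_proper_insert,
                        total_allowance = p$total_allowance,
                        min_clip = p$min_clip, threshold = p$threshold)
        cov <- vapply(ex, function(e) compute_coverage(e$proper, targets),
                      numeric(1))
        names(cov) <- names(ex)
        res <- add_vaf(res, cov)
        state$find <- res
        state$coverage <- cov
        data.table::fwrite(res$svs,
                           file.path(cfg$out_dir, "svs_unfiltered.tsv"),
                           sep = "\t")
        log$coverage <- as.list(cov)
    }
    if ("filter" %in% stages) {
        res <- need("find", "filter")
        spec <- do.call(filter_spec, cfg$filters %||% list())
        fl <- apply_filters(res$svs, spec)
        state$filter <- fl
        data.table::fwrite(fl$svs, file.path(cfg$out_dir, "svs_filtered.tsv"),
                           sep = "\t")
        data.table::fwrite(fl$attrition,
                           file.path(cfg$out_dir, "attrition.tsv"), sep = "\t")
        write_bnd_vcf(fl$svs, genome, file.path(cfg$out_dir, "svs.vcf"))
        log$n_svs_filtered <- nrow(fl$svs)
    }
    if ("genotype" %in% stages) {
        ex <- need("extract", "genotype")
        regions <- c(GenomicRanges::granges(targets$targets),
                     GenomicRanges::granges(targets$adjacent))
        proper <- data.table::rbindlist(lapply(ex, `[[`, "proper"),
                                        fill = TRUE)
        state$genotype <- build_haplotypes(proper, genome, regions,
                                           min_depth = p$min_depth,
                                           min_allele_fraction =
                                               p$min_allele_fraction)
        data.table::fwrite(state$genotype,
                           file.path(cfg$out_dir, "haplotypes.tsv"),
                           sep = "\t")
    }
    if ("stats" %in% stages) {
        res <- need("find", "stats")
        hap <- need("genotype", "stats")
        svin <- if (!is.null(state$filter)) state$filter$svs else res$svs
        dn <- call_denovo(svin, hap, genome)
        state$stats <- dn
        data.table::fwrite(dn$variants,
                           file.path(cfg$out_dir, "denovo_variants.tsv"),
                           sep = "\t")
        if (nrow(dn$variants)) {
            cov <- distance_coverage(dn$informative,
                                     unique(dn$variants$sv_id))
            pt <- junction_proximity_test(dn$variants$dist, cov,
                                          iterations = p$iterations,
                                          seed = cfg$seed)
            state$stats$test <- pt
            data.table::fwrite(data.table::data.table(
                n_variants = pt$n_variants,
                n_informative = dn$n_informative,
                observed_median = pt$observed_median,
                p_value = pt$p_value, iterations = pt$iterations,
                seed = cfg$seed),
                file.path(cfg$out_dir, "junction_proximity.tsv"), sep = "\t")
        }
    }
    saveRDS(state, state_path)
    yaml::write_yaml(log, file.path(cfg$out_dir, "run_log.yaml"))
    invisible(state)
}
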