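## Pipeline orchestration: a single validated config drives
## simulate/load -> cluster -> depth filter -> homeolog resolution ->
## multilocus phasing -> male-specific locus analysis, with a manifest
## (versions, config hash, per-stage record counts) for reproducibility.

.default_params <- function() {
  list(depth_factor = 10L, identity_floor = 0.8, min_cluster_reads = 5L,
       mask_threshold = 0.7, max_allelic_div = 0.02, denovo_cost = 0.05,
       boot_reps = 100L, support_threshold = 95, min_presence = 0.5,
       y_support_threshold = 70)
}

#' Read and validate a pipeline configuration
#'
#' A single YAML (or list) holds the run seed, the data source (either a
#' `simulate` block or an `input` block with paths) and the module
#' parameters. Unknown keys are rejected.
#'
#' @param config path to a YAML file, or a list.
#' @return validated config list with defaults filled in.
#' @export
readRunConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .stop_if(!is.list(config), "config must be a list or a YAML path")
  known_top <- c("seed", "output_dir", "simulate", "input", "params")
  unknown <- setdiff(names(config), known_top)
  .stop_if(length(unknown) > 0,
           paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  .stop_if(is.null(config$seed), "config must set a seed")
  .stop_if(is.null(config$simulate) == is.null(config$input),
           "config must set exactly one of 'simulate' or 'input'")
  if (!is.null(config$simulate)) {
    known_sim <- c("design", "depth", "dispersion", "sub", "ins", "del")
    .stop_if(!is.null(config$simulate$design) &&
               !config$simulate$design %in% c("default", "toy"),
             "simulate$design must be 'default' or 'toy'")
    unknown <- setdiff(names(config$simulate), known_sim)
    .stop_if(length(unknown) > 0,
             paste("unknown simulate key(s):", paste(unknown, collapse = ", ")))
  }
  if (!is.null(config$input)) {
    known_in <- c("reads_dir", "loci_fasta", "sample_sheet")
    unknown <- setdiff(names(config$input), known_in)
    .stop_if(length(unknown) > 0,
             paste("unknown input key(s):", paste(unknown, collapse = ", ")))
    .stop_if(!all(known_in %in% names(config$input)),
             "input block needs reads_dir, loci_fasta and sample_sheet")
  }
  defaults <- .default_params()
  unknown <- setdiff(names(config$params), names(defaults))
  .stop_if(length(unknown) > 0,
           paste("unknown params key(s):", paste(unknown, collapse = ", ")))
  config$params <- utils::modifyList(defaults, config$params %||% list())
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate pipeline inputs
#'
#' Structural checks ahead of any computation: sample sheet columns, even
#' ploidies, known sex phenotypes, allowed locus classes, duplicate
#' identifiers. Failures are reported, not raised.
#'
#' @param samples sample sheet data.frame.
#' @param loci a [LocusSet-class] or a data.frame with `locus` and `class`.
#' @param reads optional nested read list (samples must be known).
#' @return data.frame of failures (`check`, `id`, `message`); zero rows when
#'   clean.
#' @export
validateInputs <- function(samples, loci, reads = NULL) {
  bad <- list()
  note <- function(check, id, msg)
    bad[[length(bad) + 1L]] <<- data.frame(check = check, id = id,
                                           message = msg,
                                           stringsAsFactors = FALSE)
  need <- c("sample", "lineage", "sex", "ploidy")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    note("sample_sheet", "-", paste("missing column(s):", paste(miss, collapse = ", ")))
  else {
    for (i in seq_len(nrow(samples))) {
      if (samples$ploidy[i] %% 2 != 0 || samples$ploidy[i] < 2)
        note("ploidy", samples$sample[i],
             paste("ploidy must be even and >= 2, got", samples$ploidy[i]))
      if (!samples$sex[i] %in% c("male", "female", "monoecious"))
        note("sex", samples$sample[i], paste("unknown sex phenotype:", samples$sex[i]))
    }
    dup <- samples$sample[duplicated(samples$sample)]
    for (d in unique(dup)) note("duplicate_sample", d, "duplicated sample id")
  }
  if (is(loci, "LocusSet")) {
    ldf <- data.frame(locus = locusNames(loci), class = locusClass(loci))
  } else ldf <- loci
  for (i in seq_len(nrow(ldf)))
    if (!ldf$class[i] %in% LOCUS_CLASSES)
      note("locus_class", ldf$locus[i], paste("unknown locus class:", ldf$class[i]))
  dup <- ldf$locus[duplicated(ldf$locus)]
  for (d in unique(dup)) note("duplicate_locus", d, "duplicated locus id")
  if (!is.null(reads)) {
    unknown <- setdiff(names(reads), samples$sample)
    for (u in unknown) note("reads_sample", u, "reads for a sample not in the sheet")
  }
  if (!length(bad))
    return(data.frame(check = character(0), id = character(0),
                      message = character(0)))
  do.call(rbind, bad)
}

.config_hash <- function(config) {
  config$output_dir <- NULL          # paths are not analysis parameters
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(config, f)
  unname(tools::md5sum(f))
}

#' Run the full pipeline
#'
#' Executes simulate/load, read clustering and consensus, depth filtering,
#' homeolog resolution, multilocus phasing over the four locus subsets, and
#' the male-specific locus analysis, in order. Outputs (FASTA, TSV, Newick,
#' JSON manifest) are written under `output_dir` when set. A rerun with the
#' same config and inputs reproduces the manifest counts exactly.
#'
#' @param config a config list or YAML path, see [readRunConfig()].
#' @return list with `consensus`, `filter`, `groups`, `bundles`,
#'   `sexlinked`, `validation` and `manifest`.
#' @export
runPipeline <- function(config) {
  config <- readRunConfig(config)
  p <- config$params
  ## stage 0: data
  if (!is.null(config$simulate)) {
    em <- readErrorModel(sub = config$simulate$sub %||% 0.01,
                         ins = config$simulate$ins %||% 0.05,
                         del = config$simulate$del %||% 0.05)
    toy <- identical(config$simulate$design, "toy")
    sim <- simulateDataset(
      design = if (toy) toyDesign() else defaultDesign(),
      loci = if (toy) toyLoci(seed = config$seed) else NULL,
      error_model = em,
      depth = config$simulate$depth %||% 30,
      seed = config$seed,
      dispersion = config$simulate$dispersion %||% "poisson")
    data <- list(reads = sim@reads, samples = sim@samples, loci = sim@loci)
  } else {
    sim <- NULL
    data <- readAmpliconData(config$input$reads_dir, config$input$loci_fasta,
                             config$input$sample_sheet)
  }
  validation <- validateInputs(data$samples, data$loci, data$reads)
  .stop_if(nrow(validation) > 0,
           paste("input validation failed:",
                 paste(validation$check, validation$id, validation$message,
                       collapse = "; ")))
  ## stage 1: cluster + consensus
  cons <- processReads(data, identity_floor = p$identity_floor,
                       min_cluster_reads = p$min_cluster_reads,
                       mask_threshold = p$mask_threshold)
  ## stage 2: depth filter
  flt <- depthFilter(cons, data$samples, factor = p$depth_factor,
                     loci = data$loci)
  ## stage 3: homeolog resolution
  hg <- resolveHomeologs(flt$retained, data$samples, data$loci,
                         max_allelic_div = p$max_allelic_div)
  ## stage 4: multilocus phasing + subset trees
  bundles <- runSubsets(hg, data$samples, data$loci, boot_reps = p$boot_reps,
                        seed = config$seed,
                        support_threshold = p$support_threshold,
                        max_allelic_div = p$max_allelic_div,
                        denovo_cost = p$denovo_cost,
                        min_presence = p$min_presence)
  ## stage 5: male-specific locus
  sexlinked <- NULL
  ms <- locusNames(data$loci)[locusClass(data$loci) == "male_specific"]
  if (length(ms)) {
    pa <- presenceAbsence(flt$retained, data$samples, data$loci,
                          excluded = flt$excluded)
    ycons <- consensusSubset(flt$retained, locus = ms[1L])
    yinfo <- consensusInfo(ycons)
    yaln <- NULL; ytree <- NULL; indels <- NULL; intro <- NULL
    if (nrow(yinfo) >= 3) {
      yseqs <- stats::setNames(as.character(consensusSeqs(ycons)), yinfo$sample)
      yaln <- alignSequences(yseqs,
                             center = as.character(refSequences(data$loci)[[ms[1L]]]))
      indels <- sharedIndels(yaln, min_len = 2L)
      if (length(yseqs) >= 4) {
        ytree <- bootstrapSupport(yaln, n_reps = p$boot_reps, seed = config$seed)
        if (!is.null(bundles$all$tree))
          intro <- introgressionTest(ytree, bundles$all$tree, data$samples,
                                     support_threshold = p$y_support_threshold)
      }
    }
    sexlinked <- list(presence = pa, alignment = yaln, tree = ytree,
                      indels = indels, introgression = intro)
  }
  ## manifest
  n_reads <- sum(vapply(data$reads, function(s) sum(vapply(s, length, 1L)), 1L))
  manifest <- list(
    package_version = as.character(utils::packageVersion("homeophase")),
    r_version = R.version.string,
    config_hash = .config_hash(config),
    seed = config$seed,
    counts = list(
      samples = nrow(data$samples), loci = length(locusNames(data$loci)),
      reads = n_reads, consensus = length(consensusSeqs(cons)),
      retained = length(consensusSeqs(flt$retained)),
      excluded_pairs = nrow(flt$excluded),
      homeolog_groups = sum(homeologAssignment(hg)$representative),
      phased_rows = vapply(bundles, function(b)
        length(phasedAlignment(b$matrix)), 1L),
      alignment_bp = vapply(bundles, function(b) {
        a <- phasedAlignment(b$matrix)
        if (length(a)) Biostrings::width(a)[1L] else 0L
      }, 1L),
      introgression_flags = if (!is.null(sexlinked$introgression))
        sum(sexlinked$introgression$report$status == "introgression_candidate")
      else NA_integer_))
  res <- list(consensus = cons, filter = flt, groups = hg, bundles = bundles,
              sexlinked = sexlinked, validation = validation,
              manifest = manifest, sim = sim)
  if (!is.null(config$output_dir)) .write_outputs(res, data, config)
  res
}

.write_outputs <- function(res, data, config) {
  dir <- config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeConsensusFasta(res$filter$retained, file.path(dir, "consensus.fasta"))
  utils::write.table(res$filter$report, file.path(dir, "depth_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(homeologAssignment(res$groups),
                     file.path(dir, "homeolog_groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(separationDiagnostic(res$groups),
                     file.path(dir, "separation_diagnostic.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(res$bundles)) {
    b <- res$bundles[[nm]]
    writePhasedFasta(b$matrix, file.path(dir, sprintf("phased_%s.fasta", nm)))
    utils::write.table(phasingTrace(b$matrix),
                       file.path(dir, sprintf("trace_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(b$tree))
      writeNewick(b$tree, file.path(dir, sprintf("tree_%s.nwk", nm)))
    if (!is.null(b$clades))
      utils::write.table(b$clades, file.path(dir, sprintf("clades_%s.tsv", nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sx <- res$sexlinked
  if (!is.null(sx)) {
    utils::write.table(sx$presence$matrix, file.path(dir, "presence_absence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(sx$indels))
      utils::write.table(sx$indels, file.path(dir, "y_indels.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(sx$tree)) writeNewick(sx$tree, file.path(dir, "tree_y.nwk"))
    if (!is.null(sx$introgression))
      jsonlite::write_json(sx$introgression$report,
                           file.path(dir, "introgression_report.json"),
                           dataframe = "rows", auto_unbox = TRUE)
  }
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
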