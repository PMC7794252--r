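#' Random genome sequence
#'
#' Uniform i.i.d. bases; the expected TA density is 1/16, about 6,250 TA
#' sites per 100 kb.
#'
#' @param length Genome length in bp.
#' @param id Sequence id.
#' @return A [TnGenome-class].
#' @export
randomGenome <- function(length, id = "chr") {
  TnGenome(paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                 collapse = ""), id = id)
}

#' Tile a genome with synthetic gene annotations
#'
#' Splits the genome into `nGenes` blocks of roughly equal size; each gene
#' occupies the central `geneFraction` of its block, leaving intergenic
#' gaps between consecutive genes and at the chromosome ends.
#'
#' @param genomeLength Genome length in bp.
#' @param nGenes Number of genes.
#' @param geneFraction Fraction of each block covered by the gene.
#' @return data.frame of gene features (0-based half-open).
#' @export
tileGenes <- function(genomeLength, nGenes, geneFraction = 0.85) {
  bounds <- round(seq(0, genomeLength, length.out = nGenes + 1L))
  blockLen <- diff(bounds)
  pad <- pmax(1L, round(blockLen * (1 - geneFraction) / 2))
  start <- as.integer(bounds[-length(bounds)] + pad)
  end <- as.integer(bounds[-1L] - pad)
  data.frame(feature_id = sprintf("gene%03d", seq_len(nGenes)), kind = "gene",
             start = start, end = end,
             strand = sample(c("+", "-"), nGenes, replace = TRUE),
             stringsAsFactors = FALSE)
}

## --- config file -----------------------------------------------------------

configKeys <- c("genome", "annotation", "fitness_map", "seed",
                "saturation", "growth_factor_control", "survival_sub",
                "survival_bact", "bottleneck_control", "bottleneck_sub",
                "bottleneck_bactericidal", "n_replicates",
                "reads_per_sample", "tag_length", "barcode_length",
                "read_error_rate", "pseudocount", "min_sites", "alpha")

#' Read a flat key=value screen configuration file
#'
#' Recognized keys: genome, annotation, fitness_map (paths), seed, and the
#' [screenConfig()] parameters in snake_case (bottlenecks as
#' bottleneck_control / bottleneck_sub / bottleneck_bactericidal). Lines
#' starting with '#' and blank lines are ignored. Unknown keys and invalid
#' values are rejected with the offending field named.
#'
#' @param path Config file path.
#' @return List: `config` (a [ScreenConfig-class]), `paths` (named list),
#'   `seed` (integer or NULL).
#' @export
readScreenConfig <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, 1L) != 3L]
  if (length(bad)) stop("unparseable config line: '", bad[1L], "'")
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  unknown <- setdiff(keys, configKeys)
  if (length(unknown)) stop("unknown config key: '", unknown[1L], "'")
  if (anyDuplicated(keys)) stop("duplicate config key: '",
                                keys[duplicated(keys)][1L], "'")
  v <- stats::setNames(as.list(vals), keys)
  num <- function(key, default) {
    if (is.null(v[[key]])) return(default)
    x <- suppressWarnings(as.numeric(v[[key]]))
    if (is.na(x)) stop("config field '", key, "' is not numeric")
    x
  }
  cfg <- screenConfig(
    saturation = num("saturation", 0.63),
    growthFactorControl = num("growth_factor_control", 20),
    survivalSub = num("survival_sub", 0.17),
    survivalBact = num("survival_bact", 0.005),
    bottlenecks = c(control = num("bottleneck_control", 100000),
                    sub = num("bottleneck_sub", 8000),
                    bactericidal = num("bottleneck_bactericidal", 230)),
    nReplicates = num("n_replicates", 3),
    readsPerSample = num("reads_per_sample", 200000),
    tagLength = num("tag_length", 16),
    barcodeLength = num("barcode_length", 6),
    readErrorRate = num("read_error_rate", 0),
    pseudocount = num("pseudocount", 0.5),
    minSites = num("min_sites", 3),
    alpha = num("alpha", 0.05))
  paths <- v[intersect(c("genome", "annotation", "fitness_map"), names(v))]
  seed <- if (is.null(v$seed)) NULL else as.integer(num("seed", NA))
  list(config = cfg, paths = paths, seed = seed)
}

#' Write a screen configuration file
#' @param config A [ScreenConfig-class].
#' @param path Output path.
#' @param paths Named list of input paths (genome, annotation, fitness_map).
#' @param seed Optional seed to record.
#' @export
writeScreenConfig <- function(config, path, paths = list(), seed = NULL) {
  lines <- c(
    sprintf("%s = %s", names(paths), unlist(paths)),
    if (!is.null(seed)) sprintf("seed = %d", as.integer(seed)),
    sprintf("saturation = %g", config@saturation),
    sprintf("growth_factor_control = %g", config@growthFactorControl),
    sprintf("survival_sub = %g", config@survivalSub),
    sprintf("survival_bact = %g", config@survivalBact),
    sprintf("bottleneck_control = %g", config@bottlenecks[["control"]]),
    sprintf("bottleneck_sub = %g", config@bottlenecks[["sub"]]),
    sprintf("bottleneck_bactericidal = %g",
            config@bottlenecks[["bactericidal"]]),
    sprintf("n_replicates = %d", config@nReplicates),
    sprintf("reads_per_sample = %d", config@readsPerSample),
    sprintf("tag_length = %d", config@tagLength),
    sprintf("barcode_length = %d", config@barcodeLength),
    sprintf("read_error_rate = %g", config@readErrorRate),
    sprintf("pseudocount = %g", config@pseudocount),
    sprintf("min_sites = %d", config@minSites),
    sprintf("alpha = %g", config@alpha))
  writeLines(lines, path)
  invisible(path)
}

#' Generate a self-contained toy screen dataset
#'
#' A deterministic small dataset for documentation and tests: a random
#' 5-kb genome, 40 tiled genes, 3 planted resistant genes (survival
#' multiplier 30), a toy-scaled configuration, and a ground-truth file
#' listing the planted hits. The full pipeline on this dataset runs in a
#' few seconds.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return List of file paths plus `planted` (the planted feature ids).
#' @export
makeToyScreen <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  genome <- randomGenome(5000, id = "toychr")
  genes <- tileGenes(5000, 40)
  # plant resistance only in genes with enough TA sites to clear the
  # >= 3 insertion-site filter at the default saturation
  ta <- taSites(genome)
  perGene <- vapply(seq_len(nrow(genes)), function(i)
    sum(ta >= genes$start[i] & ta < genes$end[i]), 1L)
  eligible <- genes$feature_id[perGene >= 8L]
  planted <- sort(sample(eligible, 3L))
  cfg <- screenConfig(readsPerSample = 5000,
                      bottlenecks = c(control = 2000, sub = 400,
                                      bactericidal = 120))
  p <- list(genome = file.path(dir, "genome.fasta"),
            annotation = file.path(dir, "genes.gff3"),
            fitness_map = file.path(dir, "fitness_map.tsv"),
            config = file.path(dir, "screen.config"),
            truth = file.path(dir, "planted_truth.tsv"))
  writeGenomeFasta(genome, p$genome)
  writeGenesGFF3(genes, genome, p$annotation)
  utils::write.table(
    data.frame(feature_id = planted, multiplier = 30),
    p$fitness_map, sep = "\t", quote = FALSE, row.names = FALSE)
  writeScreenConfig(cfg, p$config,
                    paths = list(genome = "genome.fasta",
                                 annotation = "genes.gff3",
                                 fitness_map = "fitness_map.tsv"),
                    seed = seed)
  utils::write.table(
    data.frame(feature_id = planted, multiplier = 30, expected_call = "resistant"),
    p$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  c(p, list(planted = planted))
}

#' Run the full screen pipeline from a configuration file
#'
#' simulate -> sequence -> demultiplex -> map -> count -> analyze ->
#' report. Writes per-replicate FASTQ files, the site count tables, one
#' fitness table and ranked hit list per treated arm, a JSON-lines event
#' log with stage read-conservation counts, and a run manifest. Fully
#' deterministic given the seed.
#'
#' @param configPath Path to a [readScreenConfig()] file.
#' @param outdir Output directory (created if needed).
#' @param seed Seed override (default: the config file's seed).
#' @return Invisible list: `siteCounts`, `fitness` (per-arm tables),
#'   `hits`, `manifest`.
#' @export
runScreenPipeline <- function(configPath, outdir, seed = NULL) {
  cf <- readScreenConfig(configPath)
  config <- cf$config
  for (key in c("genome", "annotation", "fitness_map"))
    if (is.null(cf$paths[[key]]))
      stop("config error: missing required path '", key, "'")
  base <- dirname(normalizePath(configPath))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  gpath <- resolve(cf$paths$genome)
  apath <- resolve(cf$paths$annotation)
  fpath <- resolve(cf$paths$fitness_map)
  for (p in c(gpath, apath, fpath))
    if (!file.exists(p)) stop("config error: input file not found: ", p)
  if (is.null(seed)) seed <- cf$seed
  if (is.null(seed)) stop("config error: no seed in config and none supplied")

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  events <- file.path(outdir, "events.jsonl")
  cat(NULL, file = events)
  log <- function(stage, ...) {
    rec <- c(list(stage = stage), list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = events, append = TRUE)
    message("[", stage, "] ", paste(names(rec)[-1L], unlist(rec[-1L]),
                                    sep = "=", collapse = " "))
  }

  genome <- readGenomeFasta(gpath)
  genes <- readGenesGFF3(apath)
  catalog <- featureCatalog(genes, genome)
  fmap <- utils::read.delim(fpath, stringsAsFactors = FALSE)
  fitness <- fitnessMap(catalog, stats::setNames(fmap$multiplier,
                                                 fmap$feature_id))
  ta <- taSites(genome)
  log("annotate", genome_bp = length(genome), ta_sites = length(ta),
      features = nrow(features(catalog)))

  set.seed(seed)
  screen <- simulateScreen(ta, catalog, config, fitness)
  log("simulate", clones = length(screen$library),
      samples = length(screen$samples))

  barcodes <- defaultBarcodes()
  index <- buildTagIndex(genome, config@tagLength, ta)
  mapped <- list()
  fastqs <- character(0)
  for (r in seq_len(config@nReplicates)) {
    reads <- list()
    for (g in names(barcodes)) {
      nm <- sprintf("%s_rep%d", g, r)
      reads[[g]] <- generateReads(screen$samples[[nm]], genome, config,
                                  barcodes[[g]])
    }
    seqs <- unlist(lapply(reads, `[[`, "sequences"), use.names = FALSE)
    nms <- unlist(lapply(reads, `[[`, "names"), use.names = FALSE)
    ord <- sample.int(length(seqs))
    fq <- file.path(outdir, sprintf("reads_rep%d.fastq", r))
    writeReadsFastq(seqs[ord], nms[ord], fq)
    fastqs <- c(fastqs, fq)
    log("sequence", replicate = r, reads = length(seqs))

    dm <- demultiplex(seqs[ord], barcodes)
    assigned <- sum(!is.na(dm$group))
    stopifnot(assigned + sum(is.na(dm$group)) == length(seqs))
    for (g in names(barcodes)) {
      mp <- mapTags(dm$tags[[g]], index)
      mapped[[sprintf("%s_rep%d", g, r)]] <- mp
      log("map", replicate = r, group = g, assigned = length(dm$tags[[g]]),
          unique = sum(mp$status == "unique"),
          ambiguous = sum(mp$status == "ambiguous"),
          unmapped = sum(mp$status == "unmapped"))
    }
    log("demux", replicate = r, assigned = assigned,
        rejected = sum(is.na(dm$group)))
  }

  sc <- countSites(mapped, group = screen$groups)
  writeSiteCounts(sc, file.path(outdir, "site_counts.tsv"))
  writeSiteCounts(collapseOrientations(sc),
                  file.path(outdir, "site_counts_by_position.tsv"))
  log("count", sites = nrow(sc),
      mapped_reads = sum(assay(sc, "counts")))

  reps <- seq_len(config@nReplicates)
  fitnessTables <- list()
  hitTables <- list()
  for (g in c("sub", "bactericidal")) {
    ft <- featureFitness(sc, catalog,
                         treated = sprintf("%s_rep%d", g, reps),
                         control = sprintf("control_rep%d", reps),
                         pseudocount = config@pseudocount,
                         minSites = config@minSites, alpha = config@alpha)
    hits <- rankHits(ft, alpha = config@alpha, direction = "resistant")
    utils::write.table(ft, file.path(outdir, sprintf("fitness_%s.tsv", g)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(hits, file.path(outdir, sprintf("hits_%s.tsv", g)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    fitnessTables[[g]] <- ft
    hitTables[[g]] <- hits
    log("analyze", comparison = g, features_tested = sum(ft$passes_min_sites),
        resistant_hits = nrow(hits))
  }

  manifest <- list(
    package = "tnscreen",
    version = as.character(utils::packageVersion("tnscreen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_file = normalizePath(configPath),
    inputs = list(genome = gpath, annotation = apath, fitness_map = fpath),
    config = list(
      saturation = config@saturation,
      growth_factor_control = config@growthFactorControl,
      survival_sub = config@survivalSub,
      survival_bact = config@survivalBact,
      bottlenecks = as.list(config@bottlenecks),
      n_replicates = config@nReplicates,
      reads_per_sample = config@readsPerSample,
      tag_length = config@tagLength,
      barcode_length = config@barcodeLength,
      read_error_rate = config@readErrorRate,
      pseudocount = config@pseudocount,
      min_sites = config@minSites,
      alpha = config@alpha),
    outputs = list(fastq = fastqs,
                   site_counts = file.path(outdir, "site_counts.tsv")),
    counts = list(clones = length(screen$library), sites = nrow(sc),
                  mapped_reads = sum(assay(sc, "counts"))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log("report", manifest = file.path(outdir, "manifest.json"))
  invisible(list(siteCounts = sc, fitness = fitnessTables, hits = hitTables,
                 manifest = manifest))
}
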