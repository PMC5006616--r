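# End-to-end orchestration: homology -> structural -> secondary ->
# finalize -> classify -> date -> distribution stats.

.configHash <- function(config) {
  flat <- rapply(config, function(x)
    if (is.function(x)) paste(deparse(x), collapse = "") else x,
    how = "unlist")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(flat), as.character(flat), sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

#' Assemble a pipeline configuration
#'
#' Inputs may be file paths (FASTA, BLAST tabular TSV, RepeatMasker .out,
#' GFF3) or in-memory objects from [simulateGenome()]. Referenced files are
#' checked at construction so a bad path fails before any stage runs.
#'
#' @param genome genome FASTA path or `DNAStringSet` (required).
#' @param hits BLAST-style hit table (path or data.frame) for the homology
#'   stage; optional.
#' @param repeatMaskerOut RepeatMasker `.out` path or a
#'   `list(ltr=, other=)` of `GRanges`; optional.
#' @param reciprocalHits reciprocal-search best hits (`element_id`,
#'   `evalue`, ...); optional — without it homology records count as
#'   validated.
#' @param secondaryHits SIE-query-vs-genome hit table for the secondary
#'   stage; optional.
#' @param trna tRNA FASTA path or `DNAStringSet`; optional.
#' @param domainHits classification hit table (`element_id`, `domain`,
#'   `kind`, `e_value`, `lineage`); optional.
#' @param genes gene-span `GRanges` or GFF3 path; optional.
#' @param transcripts named list of stranded transcript `GRanges`; optional.
#' @param detector,filter,thresholds parameter objects.
#' @param rate substitution rate for dating.
#' @param seed RNG seed recorded in all outputs.
#' @param outdir optional output directory.
#' @return a list of class `ltrPipelineConfig`.
#' @export
pipelineConfig <- function(genome, hits = NULL, repeatMaskerOut = NULL,
                           reciprocalHits = NULL, secondaryHits = NULL,
                           trna = NULL, domainHits = NULL, genes = NULL,
                           transcripts = NULL,
                           detector = DetectorParams(),
                           filter = FilterParams(),
                           thresholds = EvidenceThresholds(),
                           rate = GALLIFORMES_RATE, seed = 1L,
                           outdir = NULL) {
  cfg <- as.list(environment())
  for (nm in c("genome", "hits", "repeatMaskerOut", "trna", "genes")) {
    x <- cfg[[nm]]
    if (is.character(x) && !file.exists(x))
      stop("input file for '", nm, "' does not exist: ", x)
  }
  class(cfg) <- "ltrPipelineConfig"
  cfg
}

.loadGenome <- function(x) {
  if (is.character(x)) x <- readDNAStringSet(x)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Run the full annotation pipeline
#'
#' Stages run in order: homology filtering and merging (with conflict filter
#' and reciprocal validation), structural detection, secondary expansion,
#' final merge with provenance accounting, lineage classification, insertion
#' dating, and distribution statistics. Deterministic given the config and
#' seed; every report carries the config hash and seed.
#'
#' @param config an [pipelineConfig()] object.
#' @return a list with `annotation`, `provenance`, `structural`, `homology`,
#'   `secondary`, `classification`, `ages`, `density`, `clusters`,
#'   `profile`, `expression`, `meta` (config hash, seed, stage counts).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "ltrPipelineConfig"))
  set.seed(config$seed)
  meta <- list(config_hash = .configHash(config), seed = config$seed,
               counts = list())
  genome <- .loadGenome(config$genome)
  gi <- GenomeIndex(setNames(width(genome), names(genome)))

  # --- stage 1: homology ---
  hom <- GRanges()
  rmOther <- GRanges()
  if (!is.null(config$hits)) {
    hits <- if (is.character(config$hits)) readBlastTab(config$hits) else
      config$hits
    hom <- filterHomologyHits(hits, config$filter)
  }
  if (!is.null(config$repeatMaskerOut)) {
    rm <- if (is.character(config$repeatMaskerOut))
      readRepeatMaskerOut(config$repeatMaskerOut) else config$repeatMaskerOut
    if (length(rm$ltr))
      hom <- c(hom, annotationSet(granges(rm$ltr), source = "homology"))
    rmOther <- rm$other
  }
  meta$counts$homology_raw <- length(hom)
  hom <- mergeAnnotations(hom, maxGap = config$filter@mergeGap, genome = gi)
  mcols(hom)$source <- rep("homology", length(hom))
  hom <- applyConflictFilter(hom, rmOther, config$filter)
  meta$counts$homology_filtered <- length(hom)
  hom <- reciprocalValidate(hom, config$reciprocalHits, config$filter)
  if (is.null(config$reciprocalHits))
    mcols(hom)$validated <- rep(TRUE, length(hom))

  # --- stage 2: structural ---
  trna <- if (is.character(config$trna)) readDNAStringSet(config$trna) else
    config$trna
  struct <- callStructuralElements(genome, config$detector, trna,
                                   thresholds = config$thresholds)
  sie <- struct[if (length(struct)) mcols(struct)$accepted else FALSE]
  meta$counts$structural_candidates <- length(struct)
  meta$counts$structural_accepted <- length(sie)

  # --- stage 3: secondary ---
  sec <- GRanges()
  if (!is.null(config$secondaryHits)) {
    sh <- if (is.character(config$secondaryHits))
      readBlastTab(config$secondaryHits) else config$secondaryHits
    existing <- c(granges(hom), granges(sie))
    sec <- secondaryExpand(sh, existing, config$filter)
  }
  meta$counts$secondary <- length(sec)

  # --- stage 4: finalize ---
  fin <- finalizeAnnotation(hom, granges(sie), sec, config$filter)
  meta$counts$final <- length(fin$annotation)

  # --- stage 5: classification ---
  classification <- NULL
  if (!is.null(config$domainHits) && nrow(config$domainHits))
    classification <- classifyElements(config$domainHits, config$thresholds)

  # --- stage 6: dating ---
  ages <- NULL
  if (length(sie)) {
    ident <- vapply(seq_along(sie), function(i) {
      m <- mcols(sie)[i, ]
      chromSeq <- genome[[as.character(seqnames(sie))[i]]]
      ltrIdentity(subseq(chromSeq, m$ltr5_start, m$ltr5_end),
                  subseq(chromSeq, m$ltr3_start, m$ltr3_end))
    }, 0)
    ages <- estimateInsertionAge(ident, rate = config$rate,
                                 elementId = mcols(sie)$element_id)
  }

  # --- stage 7: distribution stats ---
  genes <- config$genes
  if (is.character(genes)) {
    gg <- import(genes)
    genes <- gg[mcols(gg)$type %in% "gene"]
  }
  density <- chromosomeDensityTable(fin$annotation, gi)
  clusters <- callClusters(sie)
  profile <- if (!is.null(genes) && length(genes))
    tuDistanceProfile(fin$annotation, tus = genes) else NULL
  expression <- if (!is.null(config$transcripts) && length(sie))
    classifyExpressionSupport(sie, config$transcripts) else NULL

  res <- list(annotation = fin$annotation, provenance = fin$provenance,
              homology = hom, structural = struct, secondary = sec,
              classification = classification, ages = ages,
              density = density, clusters = clusters, profile = profile,
              expression = expression, meta = meta)
  if (!is.null(config$outdir)) writePipelineReports(res, config$outdir)
  res
}

#' Write pipeline reports
#'
#' Emits the final annotation GFF3, a provenance coverage TSV, the age and
#' classification tables, density and cluster reports, and a JSON metadata
#' file carrying the config hash and seed.
#'
#' @param res [runPipeline()] result.
#' @param outdir output directory.
#' @return invisibly the directory.
#' @export
writePipelineReports <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(outdir, f)
  hdr <- sprintf("# ltrscape config=%s seed=%d", res$meta$config_hash,
                 res$meta$seed)
  writeAnnotations(res$annotation, fp("annotation.gff3"))
  prov <- data.frame(category = names(res$provenance$exclusive),
                     bp = as.numeric(res$provenance$exclusive))
  writeLines(hdr, fp("provenance.tsv"))
  suppressWarnings(write.table(prov, fp("provenance.tsv"), sep = "\t",
                               quote = FALSE, row.names = FALSE,
                               append = TRUE))
  for (nm in c("ages", "classification", "density", "expression")) {
    if (!is.null(res[[nm]])) {
      writeLines(hdr, fp(paste0(nm, ".tsv")))
      suppressWarnings(write.table(res[[nm]], fp(paste0(nm, ".tsv")),
                                   sep = "\t", quote = FALSE,
                                   row.names = FALSE, append = TRUE))
    }
  }
  if (length(res$clusters)) {
    cl <- res$clusters
    mcols(cl)$member_ids <- NULL
    export(cl, fp("clusters.gff3"), format = "gff3")
  }
  if (!is.null(res$profile))
    write_json(list(meta = list(config = res$meta$config_hash,
                                seed = res$meta$seed),
                    counts = as.list(res$profile$counts),
                    total = res$profile$total),
               fp("profile.json"), auto_unbox = TRUE)
  write_json(res$meta, fp("run_meta.json"), auto_unbox = TRUE)
  invisible(outdir)
}
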