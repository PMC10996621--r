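#' Read and validate a pipeline run configuration
#'
#' The configuration is a YAML document (or an equivalent named list)
#' with blocks \code{simulate} (or \code{genomes}), \code{filters},
#' \code{thresholds}, \code{oligos}, plus top-level \code{seed} and
#' \code{out_dir}. Missing optional values take the package defaults;
#' a missing required field raises an error naming the field.
#'
#' @param config Path to a YAML file, or a named list.
#' @return The validated, defaults-filled configuration list.
#' @export
readRunConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  need <- function(field) {
    if (is.null(config[[field]]))
      stop("config validation: missing required field '", field, "'")
  }
  need("out_dir")
  if (is.null(config$simulate) && is.null(config$genomes))
    stop("config validation: missing required field 'simulate' (or 'genomes')")
  if (!is.null(config$genomes)) {
    for (f in c("reference", "model")) {
      if (is.null(config$genomes[[f]]))
        stop("config validation: missing required field 'genomes/", f, "'")
      if (!file.exists(config$genomes[[f]]))
        stop("config validation: file not found for 'genomes/", f, "': ",
             config$genomes[[f]])
    }
  }
  config$seed <- as.integer(config$seed %||% 1L)
  fdef <- list(min_len = 1000L, max_len = 8750L)
  tdef <- list(recency_threshold = 0.01, proximity = 10000L,
               flank = 50000L, min_anchor = 500L, tsd_min = 2L,
               tsd_max = 20L, max_merge_gap = 500L,
               min_seed_kmer = 15L, min_hit_len = 80L,
               max_divergence = 0.1, intact_fraction = 0.95)
  config$filters <- utils::modifyList(fdef, config$filters %||% list())
  config$thresholds <- utils::modifyList(tdef, config$thresholds %||% list())
  for (nm in names(config$thresholds)) {
    v <- config$thresholds[[nm]]
    if (!is.numeric(v) || v <= 0)
      stop("config validation: threshold '", nm, "' must be positive")
  }
  config
}

writeGenomeFasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — simulate (or load),
#' annotate, gag, recency, polymorph, oligo — writing every stage
#' output plus a manifest of file checksums to \code{out_dir}. All
#' randomness derives from the single top-level seed, so a rerun with
#' an identical configuration is byte-identical for deterministic
#' stages. A stage failure halts the run with a stage-named error;
#' outputs of completed stages are retained.
#'
#' @param config Path to a YAML configuration or a named list (see
#'   \code{\link{readRunConfig}}).
#' @return Invisibly, a list with the effective config, the in-memory
#'   stage results, and the manifest \code{data.frame}.
#' @export
runPipeline <- function(config) {
  cfg <- readRunConfig(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  files <- character(0)
  emit <- function(f) files <<- c(files, f)
  stage <- function(name, expr) {
    message("[", name, "] running")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  th <- cfg$thresholds

  ## --- simulate / load -------------------------------------------------
  sim <- stage("simulate", {
    if (!is.null(cfg$simulate)) {
      args <- cfg$simulate
      args$seed <- cfg$seed
      s <- do.call(simulateErvStudy, args)
      writeGenomeFasta(s$reference, out("reference.fa")); emit("reference.fa")
      writeFamilyModel(s$model, out("family_model.fa")); emit("family_model.fa")
      writeTruthTable(rbind(s$truth, s$strainTruth), out("truth.tsv"))
      emit("truth.tsv")
      truthToBed(s$truth, out("planted_loci.bed")); emit("planted_loci.bed")
      for (nm in names(s$strains)) {
        writeGenomeFasta(s$strains[[nm]], out(paste0(nm, ".fa")))
        emit(paste0(nm, ".fa"))
      }
      s
    } else {
      ref <- Biostrings::readDNAStringSet(cfg$genomes$reference)
      names(ref) <- sub("\\s.*", "", names(ref))
      model <- readFamilyModel(cfg$genomes$model)
      strains <- list()
      for (p in cfg$genomes$strains %||% character(0)) {
        g <- Biostrings::readDNAStringSet(p)
        names(g) <- sub("\\s.*", "", names(g))
        strains[[sub("\\.(fa|fasta)$", "", basename(p))]] <- g
      }
      list(model = model, reference = ref, strains = strains, truth = NULL)
    }
  })

  ## --- annotate --------------------------------------------------------
  ann <- stage("annotate", {
    hits <- scanHits(sim$reference, sim$model,
                     minSeedKmer = th$min_seed_kmer,
                     minHitLen = th$min_hit_len,
                     maxDivergence = th$max_divergence)
    calls <- defragment(hits, maxMergeGap = th$max_merge_gap)
    tsd <- lapply(seq_along(calls), function(i)
      detectTsd(sim$reference, calls[i], minTsd = th$tsd_min,
                maxTsd = th$tsd_max))
    calls$tsd_seq <- vapply(tsd, function(x)
      if (is.null(x)) "" else x$tsd_seq, "")
    writeCalls(calls, out("calls.bed"), out("calls.tsv"))
    emit("calls.bed"); emit("calls.tsv")
    seqs <- getCallSeqs(sim$reference, calls)
    Biostrings::writeXStringSet(seqs, out("call_seqs.fa"))
    emit("call_seqs.fa")
    cens <- censusCalls(calls)
    censusDf <- data.frame(class = names(cens$by_class),
                           n = as.integer(cens$by_class))
    write.table(censusDf, out("census.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    emit("census.tsv")
    list(hits = hits, calls = calls, seqs = seqs, census = cens)
  })

  ## --- gag -------------------------------------------------------------
  gag <- stage("gag", {
    ass <- assessGagCalls(sim$reference, ann$calls, sim$model,
                          intactFraction = th$intact_fraction)
    write.table(ass[, setdiff(names(ass), "protein")], out("gag.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    emit("gag.tsv")
    intact <- ass[ass$intact, ]
    idm <- NULL
    if (nrow(intact) >= 2L) {
      prot <- setNames(intact$protein, intact$locus_id)
      idm <- proteinIdentityMatrix(prot)
      write.table(round(idm$matrix, 2), out("gag_identity.tsv"),
                  sep = "\t", quote = FALSE)
      emit("gag_identity.tsv")
    }
    list(assessments = ass, identity = idm)
  })

  ## --- recency ---------------------------------------------------------
  rec <- stage("recency", {
    kept <- lengthFilter(ann$calls, cfg$filters$min_len,
                         cfg$filters$max_len)
    if (length(kept) < 3L) {
      message("  fewer than 3 calls pass the length filter; ",
              "recency stage reports a degenerate summary")
      list(stats = recencyStats(NULL, th$recency_threshold),
           tree = NULL, kept = kept)
    } else {
      proj <- anchorAlign(getCallSeqs(sim$reference, kept),
                          consensusSeq(sim$model))
      d <- divergenceMatrix(proj)
      bad <- apply(d, 1, anyNA)
      if (any(bad)) {
        message("  dropping ", sum(bad),
                " copies with insufficient shared columns")
        d <- d[!bad, !bad, drop = FALSE]
      }
      tree <- njTree(d)
      ape::write.tree(tree, out("family_tree.nwk")); emit("family_tree.nwk")
      write.table(round(d, 6), out("divergence.tsv"), sep = "\t",
                  quote = FALSE)
      emit("divergence.tsv")
      st <- recencyStats(tree, th$recency_threshold, dist = d)
      ltr <- lapply(which(kept$structure_class == "FULL_PROVIRUS"),
                    function(i) {
        v <- ltrLtrDivergence(kept[i], sim$reference)
        data.frame(call_id = kept$call_id[i], p = v$p, jc = v$jc)
      })
      ltrDf <- if (length(ltr)) do.call(rbind, ltr) else
        data.frame(call_id = character(), p = numeric(), jc = numeric())
      write.table(ltrDf, out("ltr_ltr_divergence.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      emit("ltr_ltr_divergence.tsv")
      list(stats = st, tree = tree, dist = d, ltr = ltrDf, kept = kept)
    }
  })

  ## --- polymorph -------------------------------------------------------
  pol <- stage("polymorph", {
    if (!length(sim$strains)) {
      message("  no strain assemblies; polymorphism stage skipped")
      NULL
    } else {
      loci <- ann$calls[ann$calls$structure_class == "FULL_PROVIRUS"]
      pm <- polymorphismMatrix(sim$reference, loci, sim$strains,
                               sim$model, flank = th$flank,
                               minAnchor = th$min_anchor)
      write.table(pm$status, out("polymorphism_matrix.tsv"), sep = "\t",
                  quote = FALSE)
      emit("polymorphism_matrix.tsv")
      write.table(pm$detail, out("polymorphism_detail.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      emit("polymorphism_detail.tsv")
      pm
    }
  })

  ## --- oligo -----------------------------------------------------------
  oli <- stage("oligo", {
    oligos <- if (!is.null(cfg$oligos))
      readOligos(cfg$oligos)
    else {
      ## no oligo file: design one against the LTR just downstream of
      ## its start, the way an LTR-directed knockdown oligo is placed
      site <- substr(as.character(ltrSeq(sim$model)), 31L, 52L)
      data.frame(name = "ltr_oligo_demo", sequence = revcompChr(site),
                 chemistry = "LNA", length = 22L,
                 stringsAsFactors = FALSE)
    }
    gagIntact <- gag$assessments$intact[
      match(ann$calls$call_id, gag$assessments$locus_id)]
    reports <- lapply(seq_len(nrow(oligos)), function(i) {
      countTargets(oligos$sequence[i], ann$seqs,
                   structureClass = ann$calls$structure_class,
                   gagIntact = gagIntact, maxMismatches = 0L)
    })
    names(reports) <- oligos$name
    summ <- data.frame(
      oligo = oligos$name, length = oligos$length,
      n_total = vapply(reports, `[[`, 0L, "n_total"),
      n_copies = vapply(reports, `[[`, 0L, "n_copies"),
      n_proviral = vapply(reports, `[[`, 0L, "n_proviral"),
      n_full_gag = vapply(reports, `[[`, 0L, "n_full_gag"),
      fraction_targeted = vapply(reports, `[[`, 0, "fraction_targeted"))
    write.table(summ, out("oligo_targets.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    emit("oligo_targets.tsv")
    list(oligos = oligos, reports = reports, summary = summ)
  })

  ## --- manifest --------------------------------------------------------
  yaml::write_yaml(cfg[c("seed", "filters", "thresholds")],
                   out("run_config.yaml"))
  emit("run_config.yaml")
  files <- sort(unique(files))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(cfg$out_dir, files))),
    stringsAsFactors = FALSE)
  write.table(manifest, out("manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(config = cfg, simulate = sim, annotate = ann, gag = gag,
                 recency = rec, polymorph = pol, oligo = oli,
                 manifest = manifest))
}
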