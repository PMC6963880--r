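## End-to-end pipeline: alignment -> diversity scan -> hotspots -> markers ->
## in-silico PCR/RFLP -> report. The report is a plain list serialized to
## stable JSON (no timestamps), so reruns with identical inputs are
## byte-identical.

#' Build and validate a pipeline configuration
#'
#' @param alignment Path to an aligned FASTA/Clustal file, or an
#'   [alignment_block()].
#' @param reference Row id or index of the reference genome within the
#'   alignment (coordinate system for partitions, hotspot names and loci).
#' @param scan A [scan_config()].
#' @param primers Named list of [primer_pair()]s (default packaged set).
#' @param enzyme_assays Named list: assay name -> list(`primer` = primer-pair
#'   name, `enzyme` = enzyme name). Default: the universal trnH-psbA pair
#'   digested with PleI.
#' @param enzymes Enzyme catalog (default packaged).
#' @param annotations Optional reference feature table for hotspot naming.
#' @param resolvable_delta Gel-resolution model for marker verdicts (bp).
#' @param species_map Optional named species labels per haplotype.
#' @param out_dir Optional output directory; when set, [run_pipeline()]
#'   writes `scan.tsv`, `hotspots.bed`, `markers.json` and `report.json`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(alignment, reference = 1L, scan = scan_config(),
                            primers = default_primers(),
                            enzyme_assays = list(
                              trnH_psbA_PleI = list(primer = "trnH_psbA_universal",
                                                    enzyme = "PleI")),
                            enzymes = read_enzymes(), annotations = NULL,
                            resolvable_delta = 10L, species_map = NULL,
                            out_dir = NULL) {
  if (is.character(alignment) && !file.exists(alignment)) {
    stop("alignment file not found: ", alignment, call. = FALSE)
  }
  if (!is.character(alignment) && !inherits(alignment, "alignment_block")) {
    stop("alignment must be a file path or an alignment_block", call. = FALSE)
  }
  for (nm in names(enzyme_assays)) {
    a <- enzyme_assays[[nm]]
    if (!a$primer %in% names(primers)) {
      stop("assay ", nm, " refers to unknown primer pair ", a$primer, call. = FALSE)
    }
    get_enzyme(a$enzyme, enzymes)  # errors on unknown enzyme
  }
  structure(list(alignment = alignment, reference = reference, scan = scan,
                 primers = primers, enzyme_assays = enzyme_assays,
                 enzymes = enzymes, annotations = annotations,
                 resolvable_delta = resolvable_delta,
                 species_map = species_map, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full marker-discovery and assay-prediction pipeline
#'
#' Stages: load alignment; partition the reference genome; sliding-window
#' diversity scan; hotspot calling; partition-wise pi averages; InDel and
#' tandem-repeat extraction; marker definition for every configured primer
#' pair (per-haplotype product sizes, mean pairwise distance over the
#' amplified locus, discrimination verdict); restriction-digest prediction
#' for the configured enzyme assays. Any stage failure aborts with the stage
#' name.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list: `version`, `config_hash`, `n_sequences`,
#'   `n_columns`, `windows`, `n_windows`, `hotspots`, `partition`,
#'   `partition_pi`, `markers` (Table-style rows: name, locus, product sizes,
#'   product range, mean pairwise distance, diagnostic flag), `rflp`
#'   (per-assay, per-haplotype fragments), `events`, `tandem_repeats`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage %s failed: %s", sQuote(name),
                   conditionMessage(e)), call. = FALSE)
    })
  }

  block <- stage("load_alignment", {
    if (inherits(config$alignment, "alignment_block")) config$alignment
    else load_alignment(config$alignment)
  })
  ref <- config$reference
  ref_i <- if (is.character(ref)) match(ref, block$haplotype_ids) else ref
  if (is.na(ref_i)) stop("reference ", ref, " not in alignment", call. = FALSE)
  ref_seq <- gsub("-", "", block$rows[ref_i], fixed = TRUE)

  part <- stage("partition_genome", {
    tryCatch(suppressWarnings(partition_genome(ref_seq)),
             error = function(e) NULL)
  })
  windows <- stage("diversity_scan",
                   sliding_window_scan(block, config$scan, reference = ref_i,
                                       partition = part))
  hotspots <- stage("detect_hotspots",
                    detect_hotspots(windows, config$scan,
                                    annotations = config$annotations,
                                    block = block, reference = ref_i))
  part_pi <- if (!is.null(part) && !part$degenerate && !is.null(windows$partition)) {
    stage("partition_average_pi", partition_average_pi(windows))
  } else NULL

  events <- stage("call_indel_events", call_indel_events(block))
  trs <- stage("detect_tandem_repeats",
               detect_tandem_repeats(block, indels = events))

  markers <- stage("define_markers", {
    lapply(config$primers, function(pp) {
      mk <- define_marker(block, pp, species_map = config$species_map,
                          resolvable_delta = config$resolvable_delta,
                          events = events, trs = trs)
      ## mean pairwise distance over the amplified locus of the reference
      amp <- predict_amplicons(ref_seq, pp)
      mk$mean_pairwise_distance <- if (nrow(amp)) {
        rmap <- reference_position_map(block, ref_i)
        cols <- which(rmap >= amp$start[1L] & rmap <= amp$end[1L] &
                        block$mat[ref_i, ] != "-")
        if (length(cols) > 1L) {
          sub <- alignment_block(apply(block$mat[, min(cols):max(cols), drop = FALSE],
                                       1L, paste, collapse = ""),
                                 ids = block$haplotype_ids,
                                 region_name = pp$name)
          mean_pairwise_distance(sub, config$scan$gap_policy)$mean
        } else NA_real_
      } else NA_real_
      mk
    })
  })

  rflp <- stage("rflp_predictions", {
    lapply(config$enzyme_assays, function(a) {
      pp <- config$primers[[a$primer]]
      res <- lapply(seq_along(block$rows), function(h) {
        tmpl <- gsub("-", "", block$rows[h], fixed = TRUE)
        amp <- predict_amplicons(tmpl, pp)
        if (!nrow(amp)) return(list(amplicon = NA_integer_, fragments = numeric()))
        dg <- digest_amplicon(amp$sequence[1L], a$enzyme, config$enzymes)
        list(amplicon = amp$length[1L], fragments = dg$fragments)
      })
      stats::setNames(res, block$haplotype_ids)
    })
  })

  marker_table <- do.call(rbind, lapply(markers, function(mk) {
    data.frame(name = mk$name,
               forward = mk$primer_pair$forward, reverse = mk$primer_pair$reverse,
               product_min = mk$product_range[1L], product_max = mk$product_range[2L],
               mean_pairwise_distance = mk$mean_pairwise_distance,
               diagnostic = mk$diagnostic,
               non_universal = paste(mk$non_universal, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(marker_table) <- NULL

  report <- list(version = as.character(utils::packageVersion("cpmarker")),
                 config_hash = config_hash(config),
                 n_sequences = length(block$rows),
                 n_columns = block$column_count,
                 n_windows = nrow(windows),
                 windows = windows, hotspots = hotspots,
                 partition = if (!is.null(part)) part$intervals else NULL,
                 partition_pi = part_pi,
                 marker_table = marker_table, markers = markers,
                 rflp = rflp, events = events, tandem_repeats = trs)
  class(report) <- "pipeline_report"

  if (!is.null(config$out_dir)) write_report(report, config$out_dir, config)
  report
}

#' @noRd
config_hash <- function(config) {
  cfg <- config
  cfg$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg, tmp, version = 2L, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' @noRd
write_report <- function(report, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$windows, file.path(out_dir, "scan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(report$hotspots)) {
    hb <- report$hotspots
    hb$score <- round(1000 * hb$max_pi)
    bed <- if (all(!is.na(hb$ref_start))) {
      data.frame(start = hb$ref_start, end = hb$ref_end, name = hb$name,
                 score = hb$score)
    } else data.frame(start = hb$start, end = hb$end, name = hb$name,
                      score = hb$score)
    write_bed(bed, file.path(out_dir, "hotspots.bed"))
  }
  jsonlite::write_json(
    lapply(report$markers, function(mk) {
      list(name = mk$name, products = as.list(mk$products),
           product_range = mk$product_range, diagnostic = mk$diagnostic,
           non_universal = mk$non_universal,
           mean_pairwise_distance = mk$mean_pairwise_distance)
    }),
    file.path(out_dir, "markers.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, na = "null")
  slim <- report
  slim$markers <- NULL
  jsonlite::write_json(unclass(slim), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d sequences x %s columns; %d windows, %d hotspot(s)\n",
              x$n_sequences, format(x$n_columns, big.mark = ","),
              x$n_windows, nrow(x$hotspots)))
  if (!is.null(x$partition_pi)) {
    cat("  partition pi (headline):",
        paste(sprintf("%s=%.4g", x$partition_pi$region, x$partition_pi$headline),
              collapse = ", "), "\n")
  }
  cat("  markers:\n")
  print(x$marker_table[, c("name", "product_min", "product_max",
                           "mean_pairwise_distance", "diagnostic")])
  invisible(x)
}
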