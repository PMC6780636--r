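## Canonical table dialect: TSV, samples in rows, header of feature names,
## first column `sample_id`. CSV is accepted by sniffing the header line.

.sniffSep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

.readTable <- function(path, what) {
  sep <- .sniffSep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1L] != "sample_id")
    stop(what, ": first column must be 'sample_id' (", path, ")")
  ids <- as.character(df$sample_id)
  if (anyDuplicated(ids))
    stop(what, ": duplicate sample_id ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  df <- df[, -1L, drop = FALSE]
  if (what != "metadata") {
    for (j in seq_along(df)) {
      if (!is.numeric(df[[j]])) {
        bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))) &
                       !is.na(df[[j]]))[1L]
        stop(what, ": non-numeric cell at row ", ids[bad],
             ", column '", colnames(df)[j], "'")
      }
    }
    df <- as.matrix(df)
  }
  rownames(df) <- ids
  df
}

#' Read a paired cohort from three tables
#'
#' Reads the abundance, peak and metadata tables (TSV, or CSV by sniffing),
#' aligns them on the intersection of sample ids (with `strict = TRUE`, the
#' id sets must be identical), and renormalizes abundance rows to sum 1 so
#' either counts or proportions are accepted. Dropped samples are reported
#' via `message()`.
#'
#' @param abundancePath,peaksPath,metadataPath file paths. The metadata
#'   table needs columns `group`, `age`, `hcq`, `prednisone_gt5`,
#'   `immunosuppressant`.
#' @param strict require identical sample ids across the three tables.
#' @return A [MultiOmicCohort-class] (empty truth ledger).
#' @export
readCohort <- function(abundancePath, peaksPath, metadataPath,
                       strict = FALSE) {
  ab <- .readTable(abundancePath, "abundance")
  pk <- .readTable(peaksPath, "peaks")
  md <- .readTable(metadataPath, "metadata")
  idSets <- list(abundance = rownames(ab), peaks = rownames(pk),
                 metadata = rownames(md))
  common <- Reduce(intersect, idSets)
  if (length(common) == 0L) stop("no common sample ids across tables")
  if (strict) {
    for (nm in names(idSets)) {
      miss <- setdiff(unique(unlist(idSets)), idSets[[nm]])
      if (length(miss))
        stop("strict alignment: table '", nm, "' is missing sample(s) ",
             paste(miss, collapse = ", "))
    }
  }
  dropped <- setdiff(unique(unlist(idSets)), common)
  if (length(dropped))
    message("dropped ", length(dropped), " sample(s) not present in all ",
            "tables: ", paste(dropped, collapse = ", "))
  ab <- ab[common, , drop = FALSE]
  rs <- rowSums(ab)
  if (any(rs <= 0)) stop("abundance rows with zero total: ",
                         paste(common[rs <= 0], collapse = ", "))
  ab <- ab / rs
  md <- md[common, , drop = FALSE]
  md <- data.frame(md, check.names = FALSE)
  md$group <- factor(md$group)
  for (cc in c("age", "hcq", "prednisone_gt5", "immunosuppressant"))
    md[[cc]] <- as.numeric(md[[cc]])
  new("MultiOmicCohort", abundance = ab, peaks = pk[common, , drop = FALSE],
      sampleData = md, truth = list())
}

.writeTable <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a cohort as three TSV tables plus a truth sidecar
#'
#' @param cohort a [MultiOmicCohort-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
writeCohortTables <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("abundance.tsv", "peaks.tsv", "metadata.tsv",
                            "truth.json"))
  .writeTable(format(abundances(cohort), digits = 17, trim = TRUE,
                     scientific = TRUE), paths[1L])
  .writeTable(format(peakAreas(cohort), digits = 17, trim = TRUE,
                     scientific = TRUE), paths[2L])
  md <- sampleData(cohort)
  df <- data.frame(sample_id = rownames(md), md, check.names = FALSE)
  utils::write.table(df, paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- plantedTruth(cohort)
  truth$config <- NULL  # S4 objects do not serialize to JSON
  jsonlite::write_json(truth, paths[4L], auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(paths)
}

#' Write analysis results with a hashed manifest
#'
#' Writes each supported result object under `outDir` — [MetricSet-class]
#' as metric TSVs, [CrossCorrResult-class] as r/p_raw/p_adj/mask TSVs,
#' [ClusterModel-class] as two-column assignment TSVs, [runConfig()] as a
#' YAML echo, data.frames as TSV — and returns a manifest of every file
#' with its MD5 content hash.
#'
#' @param results named list of result objects.
#' @param outDir output directory.
#' @param overwrite allow clobbering existing files.
#' @return data.frame manifest: `file`, `md5`.
#' @export
writeResults <- function(results, outDir, overwrite = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  put <- function(name) {
    path <- file.path(outDir, name)
    if (file.exists(path) && !overwrite)
      stop("file exists (use overwrite = TRUE): ", path)
    files <<- c(files, path)
    path
  }
  writeMat <- function(m, name) .writeTable(m, put(name))
  for (nm in names(results)) {
    obj <- results[[nm]]
    if (is(obj, "MetricSet")) {
      tab <- pairwiseTable(obj)
      wm <- weightedMeans(obj)
      tab <- rbind(tab, data.frame(classA = "(weighted mean)", classB = "",
                                   n = NA, weight = NA, BA = wm["BA"],
                                   F1 = wm["F1"], AUROC = wm["AUROC"]))
      utils::write.table(tab, put(paste0(nm, "_metrics.tsv")), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      if (nrow(obj@perRepeat))
        utils::write.table(obj@perRepeat, put(paste0(nm, "_per_repeat.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    } else if (is(obj, "CrossCorrResult")) {
      writeMat(partialR(obj), paste0(nm, "_r.tsv"))
      if (!is.null(rawP(obj))) {
        writeMat(rawP(obj), paste0(nm, "_p_raw.tsv"))
        writeMat(adjustedP(obj), paste0(nm, "_p_adj.tsv"))
        writeMat(highlightMask(obj) * 1, paste0(nm, "_mask.tsv"))
      }
    } else if (is(obj, "ClusterModel")) {
      asg <- function(v) data.frame(feature = names(v), cluster = unname(v))
      utils::write.table(asg(genusClusters(obj)),
                         put(paste0(nm, "_genus_clusters.tsv")), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(asg(metaboliteClusters(obj)),
                         put(paste0(nm, "_metabolite_clusters.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else if (is(obj, "RunConfig")) {
      cfg <- unclass(obj)
      cfg$zoo <- as.character(cfg$zoo)
      yaml::write_yaml(cfg, put(paste0(nm, "_config.yaml")))
    } else if (is.data.frame(obj)) {
      utils::write.table(obj, put(paste0(nm, ".tsv")), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    } else if (is.matrix(obj)) {
      writeMat(obj, paste0(nm, ".tsv"))
    } else {
      stop("unsupported result type for '", nm, "': ", class(obj)[1L])
    }
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         row.names = NULL)
  utils::write.table(manifest, file.path(outDir, "MANIFEST.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest
}
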