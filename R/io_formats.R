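#' Cohort container for multi-region multi-omic data
#'
#' Bundles every layer the pipeline touches into one validated object.
#' Cross-references are checked at construction: every mutation, segment,
#' methylation and expression record must point at a declared sample, every
#' clinical record at a declared patient, and each patient must contribute
#' at least two tumor regions plus exactly one matched normal. Optional
#' layers (e.g. expression profiled for only part of the cohort) may be
#' empty.
#'
#' @param samples data frame with \code{patient_id}, \code{region_id},
#'   \code{tissue} (\code{tumor}/\code{normal}), \code{purity} (in (0, 1]
#'   for tumor, \code{NA} for normal, which carries no tumor content),
#'   \code{mean_depth}, \code{qscore}, \code{contamination}.
#' @param mutations MAF-like somatic call table (may have zero rows).
#' @param segments SEG-like copy-number segment table.
#' @param methylation BED-like window count table.
#' @param expression numeric matrix, genes in rows, region ids in columns.
#' @param clinical per-patient clinical table.
#' @param arms arm-definition table (\code{chrom}, \code{arm},
#'   \code{start}, \code{end}).
#' @return Object of class \code{cohort_bundle}.
#' @export
cohort_bundle <- function(samples, mutations = .empty_mutations(),
                          segments = NULL, methylation = NULL,
                          expression = NULL, clinical = NULL,
                          arms = synthetic_arm_table()) {
  stopifnot(is.data.frame(samples), nrow(samples) > 0L)
  req <- c("patient_id", "region_id", "tissue", "purity", "mean_depth",
           "qscore", "contamination")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("samples table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(samples$region_id)) {
    stop("region_id must be unique across the cohort")
  }
  tum <- samples$tissue == "tumor"
  bad_p <- tum & (is.na(samples$purity) | samples$purity <= 0 |
                    samples$purity > 1)
  if (any(bad_p)) {
    stop("tumor purity outside (0, 1] for region ",
         samples$region_id[bad_p][1L])
  }
  counts <- table(samples$patient_id, samples$tissue)
  pats <- rownames(counts)
  n_tum <- if ("tumor" %in% colnames(counts)) counts[, "tumor"] else
    rep(0L, length(pats))
  n_nrm <- if ("normal" %in% colnames(counts)) counts[, "normal"] else
    rep(0L, length(pats))
  bad <- n_tum < 2L | n_nrm != 1L
  if (any(bad)) {
    stop("patient ", pats[bad][1L],
         " needs >= 2 tumor regions and exactly 1 normal")
  }
  check_ref <- function(tbl, what) {
    if (is.null(tbl) || nrow(tbl) == 0L) return(invisible())
    unknown <- !(tbl$region_id %in% samples$region_id)
    if (any(unknown)) {
      i <- which(unknown)[1L]
      stop("referential integrity: ", what, " record ", i,
           " references unknown region '", tbl$region_id[i], "'")
    }
  }
  check_ref(mutations, "mutation")
  check_ref(segments, "segment")
  check_ref(methylation, "methylation")
  if (!is.null(expression) && ncol(expression) > 0L) {
    unknown <- !(colnames(expression) %in% samples$region_id)
    if (any(unknown)) {
      stop("referential integrity: expression column '",
           colnames(expression)[unknown][1L],
           "' references an unknown region")
    }
  }
  if (!is.null(clinical) && nrow(clinical) > 0L) {
    unknown <- !(clinical$patient_id %in% samples$patient_id)
    if (any(unknown)) {
      stop("referential integrity: clinical record for unknown patient '",
           clinical$patient_id[unknown][1L], "'")
    }
  }
  structure(list(samples = samples, mutations = mutations,
                 segments = segments, methylation = methylation,
                 expression = expression, clinical = clinical,
                 arms = arms),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  n_pat <- length(unique(x$samples$patient_id))
  cat(sprintf("Cohort bundle: %d patients, %d samples\n", n_pat,
              nrow(x$samples)))
  cat(sprintf("  mutations: %d calls | segments: %d | methylation: %d\n",
              NROW(x$mutations), NROW(x$segments), NROW(x$methylation)))
  cat(sprintf("  expression: %d genes x %d regions | clinical: %d\n",
              NROW(x$expression), NCOL(x$expression), NROW(x$clinical)))
  invisible(x)
}

#' Chromosome-arm definitions of the synthetic genome
#'
#' The small synthetic genome used by the cohort generator: four
#' chromosomes of 100 Mb, each split into a p and a q arm (0-based
#' half-open coordinates).
#'
#' @return Data frame with \code{chrom}, \code{arm}, \code{start},
#'   \code{end}.
#' @export
synthetic_arm_table <- function() {
  path <- system.file("extdata", "synthetic_arms.tsv",
                      package = "ithlayers")
  if (nzchar(path)) {
    utils::read.delim(path, stringsAsFactors = FALSE)
  } else {
    # fallback when called from a source tree
    chrom <- rep(paste0("chr", 1:4), each = 2)
    data.frame(chrom = chrom,
               arm = paste0(rep(1:4, each = 2), c("p", "q")),
               start = rep(c(0, 5e7), 4), end = rep(c(5e7, 1e8), 4),
               stringsAsFactors = FALSE)
  }
}

# column -> type spec per layer; used by the validating TSV reader
.layer_columns <- list(
  samples = c(patient_id = "c", region_id = "c", tissue = "c",
              purity = "n", mean_depth = "n", qscore = "n",
              contamination = "n"),
  mutations = c(patient_id = "c", region_id = "c", chrom = "c", pos = "n",
                ref = "c", alt = "c", gene = "c", variant_class = "c",
                alt_reads = "n", ref_reads = "n", pop_freq = "n",
                driver_role = "c"),
  segments = c(region_id = "c", chrom = "c", start = "n", end = "n",
               state = "c", arm = "c"),
  methylation = c(region_id = "c", chrom = "c", start = "n", end = "n",
                  methylated_count = "n", total_count = "n"),
  clinical = c(patient_id = "c", subtype = "c", purity_class = "c",
               stage = "c", os_months = "n", os_event = "n",
               rfs_months = "n", rfs_event = "n"),
  arms = c(chrom = "c", arm = "c", start = "n", end = "n")
)

# Read one layer TSV, checking required columns and numeric fields; extra
# columns are preserved as character but ignored downstream.
.read_layer_tsv <- function(path, layer) {
  spec <- .layer_columns[[layer]]
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character",
                           check.names = FALSE)
  miss <- setdiff(names(spec), names(tbl))
  if (length(miss)) {
    stop(path, ": missing required columns: ",
         paste(miss, collapse = ", "))
  }
  for (col in names(spec)[spec == "n"]) {
    v <- suppressWarnings(as.numeric(tbl[[col]]))
    bad <- is.na(v) & !is.na(tbl[[col]]) & !(tbl[[col]] %in% c("NA", ""))
    if (any(bad)) {
      stop(path, " line ", which(bad)[1L] + 1L,
           ": malformed numeric field '", col, "': '",
           tbl[[col]][which(bad)[1L]], "'")
    }
    tbl[[col]] <- v
  }
  tbl
}

#' Load a cohort from a manifest file
#'
#' Reads the per-layer TSV tables named by a YAML manifest and assembles a
#' validated \code{\link{cohort_bundle}}. Relative paths are resolved
#' against the manifest's directory. Layers absent from the manifest yield
#' empty collections; the samples table is required. Writing with
#' \code{\link{write_cohort}} and loading the written manifest round-trips
#' the bundle.
#'
#' @param manifest path to a YAML manifest with keys \code{samples} and
#'   optionally \code{mutations}, \code{segments}, \code{methylation},
#'   \code{expression}, \code{clinical}, \code{arms}.
#' @return A \code{\link{cohort_bundle}}.
#' @export
load_cohort <- function(manifest) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  m <- yaml::read_yaml(manifest)
  base <- dirname(normalizePath(manifest))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!file.exists(p)) p <- file.path(base, p)
    if (!file.exists(p)) stop("manifest names a missing file: ", p)
    p
  }
  samples_path <- resolve(m$samples)
  if (is.null(samples_path)) stop("manifest must name a samples table")
  samples <- .read_layer_tsv(samples_path, "samples")
  read_opt <- function(key) {
    p <- resolve(m[[key]])
    if (is.null(p)) return(NULL)
    .read_layer_tsv(p, key)
  }
  mutations <- read_opt("mutations")
  if (is.null(mutations)) mutations <- .empty_mutations()
  expression <- NULL
  ep <- resolve(m$expression)
  if (!is.null(ep)) {
    etbl <- utils::read.delim(ep, stringsAsFactors = FALSE,
                              check.names = FALSE)
    expression <- as.matrix(etbl[, -1, drop = FALSE])
    rownames(expression) <- etbl[[1L]]
    storage.mode(expression) <- "double"
  }
  arms <- read_opt("arms")
  if (is.null(arms)) arms <- synthetic_arm_table()
  cohort_bundle(samples = samples, mutations = mutations,
                segments = read_opt("segments"),
                methylation = read_opt("methylation"),
                expression = expression,
                clinical = read_opt("clinical"),
                arms = arms)
}

#' Write a cohort to TSV tables plus a manifest
#'
#' Writes each non-empty layer of the bundle to a TSV file under
#' \code{dir} and a \code{manifest.yaml} naming them, in the dialects
#' \code{\link{load_cohort}} reads back.
#'
#' @param bundle a \code{\link{cohort_bundle}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  put <- function(tbl, key) {
    if (is.null(tbl) || nrow(tbl) == 0L) return(invisible())
    fn <- paste0(key, ".tsv")
    utils::write.table(tbl, file.path(dir, fn), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest[[key]] <<- fn
  }
  put(bundle$samples, "samples")
  put(bundle$mutations, "mutations")
  put(bundle$segments, "segments")
  put(bundle$methylation, "methylation")
  put(bundle$clinical, "clinical")
  put(bundle$arms, "arms")
  if (!is.null(bundle$expression) && nrow(bundle$expression) > 0L) {
    etbl <- data.frame(gene = rownames(bundle$expression),
                       bundle$expression, check.names = FALSE,
                       stringsAsFactors = FALSE)
    utils::write.table(etbl, file.path(dir, "expression.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$expression <- "expression.tsv"
  }
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Serialise a tree to a Newick string
#'
#' @param tree an \code{\link{minimum_evolution_tree}} result
#'   (\code{ith_tree}) or an \code{ape} \code{phylo}. All leaves must be
#'   named and all edge lengths finite and non-negative.
#' @return A Newick string with branch lengths; leaf labels are region ids.
#' @export
write_newick <- function(tree) {
  phy <- if (inherits(tree, "ith_tree")) tree$phy else tree
  if (!inherits(phy, "phylo")) stop("tree must be an ith_tree or phylo")
  if (length(phy$tip.label) < 2L) stop("tree needs >= 2 leaves")
  if (any(is.na(phy$tip.label) | !nzchar(phy$tip.label))) {
    stop("all leaves must be named")
  }
  if (any(!is.finite(phy$edge.length)) || any(phy$edge.length < 0)) {
    stop("edge lengths must be finite and non-negative")
  }
  ape::write.tree(phy)
}

#' Parse a Newick string
#'
#' @param text a Newick string.
#' @return An \code{ape} \code{phylo}.
#' @export
read_newick <- function(text) {
  ape::read.tree(text = text)
}

# recursively sort list names so serialised reports diff cleanly
.sort_keys <- function(x) {
  if (is.list(x) && !is.null(names(x)) && !is.data.frame(x)) {
    x <- x[order(names(x))]
    lapply(x, .sort_keys)
  } else if (is.list(x) && !is.data.frame(x)) {
    lapply(x, .sort_keys)
  } else {
    x
  }
}

#' Write a machine-readable analysis report
#'
#' Serialises pipeline results (per-patient per-layer ITH, trunk/branch
#' proportions, trees, statistics) to JSON with sorted keys and
#' full-precision floats, so repeated runs of a deterministic pipeline
#' produce byte-identical files.
#'
#' @param results non-empty named list (typically the \code{report} field
#'   of \code{\link{run_pipeline}}'s result).
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
write_report <- function(results, path) {
  if (length(results) == 0L) stop("results must be non-empty")
  jsonlite::write_json(.sort_keys(results), path, auto_unbox = TRUE,
                       digits = NA, na = "null", null = "null",
                       dataframe = "rows")
  invisible(path)
}

#' Read a report written by \code{\link{write_report}}
#'
#' @param path JSON report file.
#' @return Nested list of report values.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
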