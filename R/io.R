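#' Read an alignment into sampler input
#'
#' Two formats are supported. The "sites" dialect is a plain-text format:
#' header lines `#NAMES <tab-separated haploid lineage names>` and
#' `#REGION <chrom> <start> <end>` (1-based inclusive), followed by one row
#' per variant position: `position<TAB>alleles` with one base per lineage in
#' NAMES order (`N` = missing; lower-case bases are valid calls), plus an
#' optional third column giving the ancestral base. Without that column the
#' ancestral allele is taken from `outgroup`'s base if given, else the
#' majority base. VCF input (via the vcfR package) uses REF as ancestral.
#' Sites with more than two observed alleles are dropped and counted.
#'
#' @param path File path.
#' @param format `"sites"` or `"vcf"`.
#' @param compress Bases per invariant compressed column (default 10).
#' @param mut_rate,recomb_rate Scalar rates or maps (see [compress_sites()]).
#' @param outgroup Optional lineage name whose allele defines the ancestral
#'   state when no ancestral column is present.
#' @param window_bp Window length; defaults to the REGION header (sites) or
#'   the maximum position (VCF).
#' @param masks Optional mask intervals (see [compress_sites()]).
#' @return An [arg_data()] object; the number of dropped multi-allelic
#'   sites is available as `attr(, "dropped_sites")`.
#' @export
load_alignment <- function(path, format = c("sites", "vcf"), compress = 10L,
                           mut_rate = 1.45e-8, recomb_rate = 5e-9,
                           outgroup = NULL, window_bp = NULL, masks = NULL) {
  format <- match.arg(format)
  if (format == "sites") {
    lines <- readLines(path)
    names_ln <- grep("^#NAMES", lines, value = TRUE)
    if (length(names_ln) != 1L)
      stop("parse error: missing #NAMES header in ", path, call. = FALSE)
    lineages <- strsplit(sub("^#NAMES\t?", "", names_ln), "\t")[[1]]
    region_ln <- grep("^#REGION", lines, value = TRUE)
    if (length(region_ln) == 1L) {
      reg <- strsplit(sub("^#REGION\t?", "", region_ln), "\t")[[1]]
      if (is.null(window_bp)) window_bp <- as.numeric(reg[3])
    }
    body <- lines[!grepl("^#", lines) & nzchar(lines)]
    pos <- integer(0); allele_rows <- list(); dropped <- 0L
    for (i in seq_along(body)) {
      f <- strsplit(body[i], "\t")[[1]]
      if (length(f) < 2L || is.na(suppressWarnings(as.integer(f[1]))))
        stop("parse error at line ", i, " of ", path, call. = FALSE)
      bases <- toupper(strsplit(f[2], "")[[1]])
      if (length(bases) != length(lineages))
        stop("parse error at line ", i, ": expected ", length(lineages),
             " bases", call. = FALSE)
      obs <- unique(bases[bases != "N"])
      if (length(obs) > 2L) { dropped <- dropped + 1L; next }
      anc <- if (length(f) >= 3L) toupper(f[3])
             else if (!is.null(outgroup) &&
                      bases[match(outgroup, lineages)] != "N")
               bases[match(outgroup, lineages)]
             else names(sort(table(bases[bases != "N"]),
                             decreasing = TRUE))[1]
      al <- ifelse(bases == "N", NA_integer_,
                   ifelse(bases == anc, 0L, 1L))
      pos <- c(pos, as.integer(f[1]))
      allele_rows[[length(allele_rows) + 1L]] <- al
    }
    if (is.null(window_bp))
      window_bp <- if (length(pos)) max(pos) else 0
    alleles <- if (length(pos)) do.call(cbind, allele_rows)
               else matrix(integer(0), length(lineages), 0)
    rownames(alleles) <- lineages
    ord <- order(pos)
    out <- compress_sites(lineages, pos[ord],
                          alleles[, ord, drop = FALSE], window_bp,
                          compress = compress, mut_rate = mut_rate,
                          recomb_rate = recomb_rate, masks = masks)
    attr(out, "dropped_sites") <- dropped
    return(out)
  }
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  pos <- as.integer(vcfR::getPOS(v))
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  dropped <- sum(multi)
  gt <- gt[!multi, , drop = FALSE]
  pos <- pos[!multi]
  # one haploid lineage per GT field entry
  samples <- colnames(gt)
  rows <- list(); lineages <- character(0)
  ploidy <- ifelse(grepl("[/|]", gt[1, ]), 2L, 1L)
  for (k in seq_along(samples)) {
    parts <- strsplit(gsub("\\|", "/", gt[, k]), "/")
    for (h in seq_len(ploidy[k])) {
      al <- vapply(parts, function(p)
        if (length(p) < h || is.na(p[h]) || p[h] == ".") NA_integer_
        else as.integer(p[h]), integer(1))
      rows[[length(rows) + 1L]] <- al
      lineages <- c(lineages,
                    if (ploidy[k] == 1L) samples[k]
                    else paste0(samples[k], "_", h))
    }
  }
  alleles <- do.call(rbind, rows)
  rownames(alleles) <- lineages
  alleles[alleles > 1L] <- 1L
  if (is.null(window_bp)) window_bp <- max(pos)
  ord <- order(pos)
  out <- compress_sites(lineages, pos[ord], alleles[, ord, drop = FALSE],
                        window_bp, compress = compress,
                        mut_rate = mut_rate, recomb_rate = recomb_rate,
                        masks = masks)
  attr(out, "dropped_sites") <- dropped
  out
}

#' Write a dataset in the sites dialect
#'
#' @param dataset A `sim_dataset` (or anything with `lineages`, `positions`,
#'   `alleles`, `window_bp`).
#' @param path Output path.
#' @param chrom Chromosome label for the REGION header.
#' @export
write_sites <- function(dataset, path, chrom = "chr1") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#NAMES\t", paste(dataset$lineages, collapse = "\t")),
             con)
  writeLines(paste0("#REGION\t", chrom, "\t1\t", dataset$window_bp), con)
  if (length(dataset$positions)) {
    al <- dataset$alleles
    for (i in seq_along(dataset$positions)) {
      bases <- ifelse(is.na(al[, i]), "N", ifelse(al[, i] == 0L, "A", "G"))
      writeLines(paste0(dataset$positions[i], "\t",
                        paste(bases, collapse = ""), "\tA"), con)
    }
  }
  invisible(path)
}

#' Write region calls as BED
#'
#' 0-based half-open intervals; name = band, score = 1000 x mean posterior,
#' and the zygosity in column 7.
#'
#' @param calls [call_regions()] output (may span several bands and
#'   individuals).
#' @param path Output path.
#' @param chrom Chromosome label.
#' @export
write_calls_bed <- function(calls, path, chrom = "chr1") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tname\tscore\tstrand\tzygosity\tindividual",
             con)
  if (nrow(calls)) {
    lines <- paste(chrom, calls$start, calls$end, calls$band,
                   round(1000 * calls$mean_posterior), ".",
                   calls$zygosity, calls$individual, sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read region calls written by [write_calls_bed()]
#' @param path BED path.
#' @return Tibble of calls.
#' @export
read_calls_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines))
    return(tibble::tibble(start = integer(), end = integer(),
                          band = character(), individual = character(),
                          zygosity = character(),
                          mean_posterior = numeric(), bp = integer()))
  f <- do.call(rbind, strsplit(lines, "\t"))
  tibble::tibble(
    start = as.integer(f[, 2]), end = as.integer(f[, 3]), band = f[, 4],
    individual = f[, 8], zygosity = f[, 7],
    mean_posterior = as.numeric(f[, 5]) / 1000,
    bp = as.integer(f[, 3]) - as.integer(f[, 2]))
}

#' Write a posterior track as bedGraph
#'
#' @param track [posterior_tracks()] output.
#' @param path Output path.
#' @param chrom Chromosome label.
#' @param value Which posterior to write (`"p_any"`, `"p_het"`, `"p_hom"`).
#' @export
write_track_bedgraph <- function(track, path, chrom = "chr1",
                                 value = "p_any") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "track type=bedGraph name=\"%s %s %s\"",
    attr(track, "band") %||% "", attr(track, "individual") %||% "", value),
    con)
  writeLines(paste(chrom, track$start_bp, track$end_bp,
                   signif(track[[value]], 6), sep = "\t"), con)
  invisible(path)
}

#' Serialize an ARG as line-based text
#'
#' One `TREE` line per local tree span and one `NODE` line per node
#' (`tree_id`, `node`, `parent`, `time_idx`, `path_id`, `leaf_label`), plus
#' `SPR` lines where the recombination event is explicitly represented.
#' Byte-identical for identical seeds.
#'
#' @param arg An [new_arg()] object.
#' @param path Output path.
#' @export
write_arg <- function(arg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#ARG\tn_col=", arg$n_col, "\tlineages=",
                    paste(arg$lineages, collapse = ",")), con)
  for (i in seq_along(arg$trees)) {
    tr <- arg$trees[[i]]
    writeLines(paste("TREE", i, arg$starts[i], arg$ends[i], sep = "\t"), con)
    for (v in seq_along(tr$parent))
      writeLines(paste("NODE", i, v, tr$parent[v], tr$time[v], tr$path[v],
                       if (v <= tr$n_leaf) tr$lineages[v] else ".",
                       sep = "\t"), con)
    if (i > 1L && !is.null(arg$sprs[[i - 1L]])) {
      s <- arg$sprs[[i - 1L]]
      writeLines(paste("SPR", i - 1L, s$pos, s$rec_key, s$rec_time,
                       s$coal_key, s$coal_time, s$coal_path, sep = "\t"),
                 con)
    }
  }
  invisible(path)
}

#' Read an ARG serialized by [write_arg()]
#' @param path Input path.
#' @return An [new_arg()] object.
#' @export
read_arg <- function(path) {
  lines <- readLines(path)
  hd <- strsplit(sub("^#ARG\t", "", lines[1]), "\t")[[1]]
  n_col <- as.integer(sub("n_col=", "", hd[1]))
  lineages <- strsplit(sub("lineages=", "", hd[2]), ",")[[1]]
  tree_ln <- grep("^TREE", lines)
  trees <- list(); starts <- integer(); ends <- integer()
  node_f <- do.call(rbind, strsplit(grep("^NODE", lines, value = TRUE), "\t"))
  for (ln in tree_ln) {
    f <- strsplit(lines[ln], "\t")[[1]]
    i <- as.integer(f[2])
    starts <- c(starts, as.integer(f[3])); ends <- c(ends, as.integer(f[4]))
    nd <- node_f[as.integer(node_f[, 2]) == i, , drop = FALSE]
    nd <- nd[order(as.integer(nd[, 3])), , drop = FALSE]
    leaf_lab <- nd[nd[, 7] != ".", 7]
    trees[[i]] <- local_tree(parent = as.integer(nd[, 4]),
                             time = as.integer(nd[, 5]),
                             path = as.integer(nd[, 6]),
                             lineages = leaf_lab)
  }
  sprs <- vector("list", max(length(trees) - 1L, 0L))
  for (ln in grep("^SPR", lines)) {
    f <- strsplit(lines[ln], "\t")[[1]]
    sprs[[as.integer(f[2])]] <- list(
      pos = as.integer(f[3]), rec_key = f[4],
      rec_time = as.integer(f[5]), coal_key = f[6],
      coal_time = as.integer(f[7]), coal_path = as.integer(f[8]))
  }
  new_arg(trees, starts, ends, sprs, n_col, lineages)
}

#' Write the standard output bundle of a sampling run
#'
#' Calls as BED, per-(band, individual) posterior bedGraphs, the chain
#' statistics log as TSV, and the final ARG.
#'
#' @param chain An `arg_chain`.
#' @param prefix Output path prefix.
#' @param threshold Posterior threshold for calls.
#' @param chrom Chromosome label.
#' @return Invisibly, the list of files written.
#' @export
write_outputs <- function(chain, prefix, threshold = 0.5, chrom = "chr1") {
  files <- character(0)
  model <- chain$model
  all_calls <- list()
  for (b in model$bands$band) {
    for (ind in model$samples$sample_id[model$samples$ploidy == 2L]) {
      tr <- posterior_tracks(chain, b, ind)
      f <- paste0(prefix, ".", b, ".", ind, ".bedGraph")
      write_track_bedgraph(tr, f, chrom = chrom)
      files <- c(files, f)
      all_calls[[length(all_calls) + 1L]] <-
        call_regions(tr, threshold = threshold)
    }
  }
  calls <- dplyr::bind_rows(all_calls)
  f <- paste0(prefix, ".calls.bed")
  write_calls_bed(calls, f, chrom = chrom)
  files <- c(files, f)
  f <- paste0(prefix, ".stats.tsv")
  utils::write.table(chain$stats, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f)
  f <- paste0(prefix, ".final.arg")
  write_arg(chain$arg, f)
  files <- c(files, f)
  invisible(files)
}
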