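#' Construct a phased haplotype panel
#'
#' A haplotype panel holds \code{2n} phased homologous chromosomes for
#' \code{n} diploid individuals over \code{m} biallelic markers, together
#' with a genetic map in centiMorgan.  Rows \code{2k-1} and \code{2k} are
#' the two chromosomes of individual \code{k}.
#'
#' @param alleles integer/numeric matrix of 0/1 alleles, \code{2n x m}.
#' @param positions_cM numeric vector of \code{m} genetic positions (cM),
#'   non-decreasing.  Exact ties are perturbed by \code{+1e-9} in input
#'   order so positions are strictly increasing.
#' @param marker_ids optional character vector of marker names.
#' @param individual_ids optional character vector of \code{n} individual
#'   names.
#' @return An object of class \code{haplotype_panel} with fields
#'   \code{alleles}, \code{positions_cM}, \code{marker_ids},
#'   \code{individual_ids}.
#' @export
haplotype_panel <- function(alleles, positions_cM, marker_ids = NULL,
                            individual_ids = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) %% 2L != 0L)
    stop("haplotype panel must have an even number of chromosome rows, got ",
         nrow(alleles))
  if (!all(alleles %in% c(0L, 1L)))
    stop("alleles must all be 0 or 1")
  m <- ncol(alleles)
  positions_cM <- as.numeric(positions_cM)
  if (length(positions_cM) != m)
    stop("length(positions_cM) != number of markers")
  if (any(diff(positions_cM) < 0))
    stop("genetic positions must be non-decreasing")
  ## break exact ties so positions are strictly increasing
  while (any(diff(positions_cM) <= 0)) {
    k <- which(diff(positions_cM) <= 0) + 1L
    positions_cM[k] <- positions_cM[k - 1L] + 1e-9
  }
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(m))
  if (is.null(individual_ids))
    individual_ids <- paste0("ind", seq_len(nrow(alleles) / 2L))
  if (length(individual_ids) != nrow(alleles) / 2L)
    stop("need one individual id per pair of chromosome rows")
  dimnames(alleles) <- NULL
  structure(list(alleles = alleles,
                 positions_cM = positions_cM,
                 marker_ids = as.character(marker_ids),
                 individual_ids = as.character(individual_ids)),
            class = "haplotype_panel")
}

#' @method print haplotype_panel
#' @export
print.haplotype_panel <- function(x, ...) {
  m <- ncol(x$alleles)
  cat("haplotype_panel:", nrow(x$alleles), "chromosomes (",
      nrow(x$alleles) / 2L, "diploid individuals ) x", m, "markers\n")
  if (m) cat("  map: ", format(x$positions_cM[1L], digits = 4), "-",
             format(x$positions_cM[m], digits = 4), "cM\n")
  invisible(x)
}

#' Number of diploid individuals / markers in a panel
#' @param panel a \code{haplotype_panel}.
#' @return integer count.
#' @export
n_individuals <- function(panel) nrow(panel$alleles) %/% 2L

#' @rdname n_individuals
#' @export
n_markers <- function(panel) ncol(panel$alleles)

#' Convert physical to genetic positions
#'
#' Uses the 1 Mb = 1 cM equivalence applied when no genetic map is
#' available.
#'
#' @param bp_positions non-decreasing base-pair positions.
#' @return positions in centiMorgan (\code{bp / 1e6}).
#' @export
physical_to_genetic <- function(bp_positions) {
  bp_positions <- as.numeric(bp_positions)
  if (any(bp_positions < 0)) stop("negative physical positions")
  if (any(diff(bp_positions) < 0)) stop("physical positions must be non-decreasing")
  bp_positions / 1e6
}

#' Per-marker minor allele frequency
#' @param panel a \code{haplotype_panel}.
#' @return numeric vector of MAFs over the 2n chromosomes.
#' @export
maf <- function(panel) {
  p <- colMeans(panel$alleles)
  pmin(p, 1 - p)
}

#' Filter markers on minor allele frequency
#'
#' Retains markers whose MAF (over the 2n chromosomes) strictly exceeds
#' \code{threshold}; map and marker ids are subset consistently.
#'
#' @param panel a \code{haplotype_panel}.
#' @param threshold MAF threshold in [0, 0.5]; default 0.05.
#' @return the filtered \code{haplotype_panel} (possibly with 0 markers).
#' @export
maf_filter <- function(panel, threshold = 0.05) {
  stopifnot(threshold >= 0, threshold <= 0.5)
  keep <- maf(panel) > threshold
  haplotype_panel(panel$alleles[, keep, drop = FALSE],
                  panel$positions_cM[keep],
                  panel$marker_ids[keep],
                  panel$individual_ids)
}

#' Subset a panel by marker index
#' @param panel a \code{haplotype_panel}.
#' @param markers integer marker indices to keep (in order).
#' @return the subset \code{haplotype_panel}.
#' @export
subset_markers <- function(panel, markers) {
  haplotype_panel(panel$alleles[, markers, drop = FALSE],
                  panel$positions_cM[markers],
                  panel$marker_ids[markers],
                  panel$individual_ids)
}

#' Enumerate sliding windows of t consecutive markers
#'
#' Every run of \code{t} consecutive markers defines one window; its tested
#' position is the unobserved center, taken as the genetic midpoint of the
#' two innermost markers (window markers \code{t/2} and \code{t/2 + 1}).
#'
#' @param panel a \code{haplotype_panel}.
#' @param t even window size, \code{t <= m}.
#' @return list of \code{m - t + 1} window specs, each a list with
#'   \code{marker_indices} (length t) and \code{tested_pos_cM}.
#' @export
enumerate_windows <- function(panel, t) {
  m <- n_markers(panel)
  if (t %% 2L != 0L)
    stop("window size t must be even (the tested center is between the two ",
         "innermost markers)")
  if (t > m) stop("window size exceeds marker count")
  lapply(seq_len(m - t + 1L), function(s) {
    idx <- s:(s + t - 1L)
    window_spec(panel, idx)
  })
}

#' Window specification over explicit marker indices
#' @param panel a \code{haplotype_panel}.
#' @param marker_indices consecutive marker indices, even count.
#' @return a window spec list (\code{marker_indices}, \code{tested_pos_cM}).
#' @export
window_spec <- function(panel, marker_indices) {
  t <- length(marker_indices)
  if (t %% 2L != 0L) stop("window must contain an even number of markers")
  inner <- marker_indices[c(t %/% 2L, t %/% 2L + 1L)]
  list(marker_indices = as.integer(marker_indices),
       tested_pos_cM = mean(panel$positions_cM[inner]))
}

#' Code the haplotypes observed in a window
#'
#' Assigns each chromosome an integer label in \code{1..kappa} identifying
#' its distinct t-marker allele pattern within the window.  Labels are given
#' in order of first appearance so runs are reproducible; frequencies are
#' label counts over the 2n chromosomes.
#'
#' @param panel a \code{haplotype_panel}.
#' @param window a window spec from \code{\link{enumerate_windows}} or
#'   \code{\link{window_spec}}; alternatively a vector of marker indices.
#' @param exclude optional marker indices to drop from the pattern (e.g. a
#'   hidden QTL marker lying inside the window).
#' @return list with \code{window}, \code{labels} (length 2n),
#'   \code{patterns} (kappa strings of 0/1), \code{freqs} (kappa
#'   frequencies summing to 1), and \code{pattern_mat} (kappa x t matrix).
#' @export
code_haplotypes <- function(panel, window, exclude = integer(0)) {
  if (!is.list(window)) window <- window_spec(panel, window)
  idx <- setdiff(window$marker_indices, exclude)
  sub <- panel$alleles[, idx, drop = FALSE]
  keys <- do.call(paste0, as.data.frame(sub))
  first <- !duplicated(keys)
  patterns <- keys[first]
  labels <- match(keys, patterns)
  freqs <- as.numeric(tabulate(labels, nbins = length(patterns))) / length(keys)
  list(window = window,
       used_indices = as.integer(idx),
       positions_cM = panel$positions_cM[idx],
       labels = labels,
       patterns = patterns,
       freqs = freqs,
       pattern_mat = sub[first, , drop = FALSE])
}

## ---------------------------------------------------------------- file IO

#' Read a phased haplotype panel
#'
#' Two formats are supported: a phased VCF (all genotypes \code{a|b},
#' biallelic sites only) and a plain whitespace-delimited 0/1 matrix with a
#' companion map file.  The plain haplotype file has one chromosome per row,
#' first column the individual id (repeated on consecutive row pairs); the
#' map file has three columns: marker id, chromosome name, position.
#'
#' @param path for \code{format = "vcf"}, the VCF path; for
#'   \code{format = "plain"}, the haplotype-matrix path.
#' @param format \code{"vcf"} or \code{"plain"}.
#' @param map_path map file path (plain format only).
#' @param map_units \code{"cM"} (default) or \code{"bp"}; base-pair maps
#'   are converted with \code{\link{physical_to_genetic}}.
#' @return a \code{haplotype_panel}.
#' @export
read_panel <- function(path, format = c("plain", "vcf"), map_path = NULL,
                       map_units = c("cM", "bp")) {
  format <- match.arg(format)
  map_units <- match.arg(map_units)
  if (format == "vcf") return(read_panel_vcf(path))
  if (is.null(map_path)) stop("plain format requires a map file (map_path)")
  hap <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(hap[[1L]])
  alleles <- as.matrix(hap[, -1L, drop = FALSE])
  if (nrow(alleles) %% 2L != 0L)
    stop("haplotype file ", path, " has an odd number of chromosome rows")
  odd <- ids[seq(1L, length(ids), by = 2L)]
  even <- ids[seq(2L, length(ids), by = 2L)]
  if (!all(odd == even))
    stop("consecutive chromosome rows must share an individual id; first ",
         "mismatch at row pair ", which(odd != even)[1L])
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) < 3L) stop("map file must have 3 columns: id, chrom, position")
  if (nrow(map) != ncol(alleles))
    stop("map file has ", nrow(map), " markers but haplotype file has ",
         ncol(alleles))
  pos <- as.numeric(map[[3L]])
  if (map_units == "bp") pos <- physical_to_genetic(pos)
  haplotype_panel(alleles, pos, marker_ids = as.character(map[[1L]]),
                  individual_ids = odd)
}

read_panel_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = 7L,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"]) | fix[, "ALT"] == "."
  if (any(multi))
    stop("non-biallelic VCF record at ", fix[which(multi)[1L], "CHROM"], ":",
         fix[which(multi)[1L], "POS"])
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  bad <- which(!grepl("^[01]\\|[01]$", gt))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(gt))
    stop("unphased or invalid genotype '", gt[bad[1L]], "' at record ",
         fix[rc[1L], "CHROM"], ":", fix[rc[1L], "POS"], " sample ",
         colnames(gt)[rc[2L]])
  }
  a1 <- matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt))
  a2 <- matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt))
  n <- ncol(gt)
  alleles <- matrix(0L, nrow = 2L * n, ncol = nrow(gt))
  alleles[seq(1L, 2L * n, by = 2L), ] <- t(a1)
  alleles[seq(2L, 2L * n, by = 2L), ] <- t(a2)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  haplotype_panel(alleles, physical_to_genetic(as.numeric(fix[, "POS"])),
                  marker_ids = ids, individual_ids = colnames(gt))
}

#' Write a panel in the plain haplotype + map format
#'
#' @param panel a \code{haplotype_panel}.
#' @param prefix output path prefix; writes \code{<prefix>.hap} and
#'   \code{<prefix>.map}.
#' @param chrom chromosome name recorded in the map file.
#' @return invisibly, the two file paths.
#' @export
write_panel <- function(panel, prefix, chrom = "1") {
  hap_path <- paste0(prefix, ".hap")
  map_path <- paste0(prefix, ".map")
  ids <- rep(panel$individual_ids, each = 2L)
  hap <- data.frame(id = ids, panel$alleles, check.names = FALSE)
  utils::write.table(hap, hap_path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  map <- data.frame(id = panel$marker_ids, chrom = chrom,
                    cM = format(panel$positions_cM, digits = 17))
  utils::write.table(map, map_path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(c(hap = hap_path, map = map_path))
}
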