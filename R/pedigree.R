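#' Construct / validate a pedigree
#'
#' A pedigree is a data frame with columns \code{id}, \code{sire},
#' \code{dam}, \code{generation}; founders have \code{NA} parents.
#' Individuals are renumbered 1..n in an order where parents precede
#' offspring; cycles are an error.
#'
#' @param id,sire,dam integer/character vectors; 0 or NA marks an unknown
#'   parent.
#' @param generation optional integer generation number (founders = 1);
#'   computed from parent depth when missing.
#' @return a \code{data.frame} of class \code{pedigree} with integer
#'   columns \code{id}, \code{sire}, \code{dam}, \code{generation} (parents
#'   as row indices, NA for founders).
#' @export
pedigree <- function(id, sire, dam, generation = NULL) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicated individual ids in pedigree")
  sire <- as.character(sire); dam <- as.character(dam)
  sire[sire %in% c("0", "", "NA")] <- NA
  dam[dam %in% c("0", "", "NA")] <- NA
  si <- match(sire, id); di <- match(dam, id)
  if (any(!is.na(sire) & is.na(si)))
    stop("unknown sire id: ", sire[!is.na(sire) & is.na(si)][1L])
  if (any(!is.na(dam) & is.na(di)))
    stop("unknown dam id: ", dam[!is.na(dam) & is.na(di)][1L])
  n <- length(id)
  ## topological depth; detects cycles
  depth <- rep(NA_integer_, n)
  pending <- rep(TRUE, n)
  for (pass in seq_len(n + 1L)) {
    ready <- which(pending &
                   (is.na(si) | !is.na(depth[si]) | !pending[si]) &
                   (is.na(di) | !is.na(depth[di]) | !pending[di]))
    ready <- ready[pending[ready]]
    if (!length(ready)) break
    d_s <- ifelse(is.na(si[ready]), 0L, depth[si[ready]])
    d_d <- ifelse(is.na(di[ready]), 0L, depth[di[ready]])
    depth[ready] <- pmax(d_s, d_d, na.rm = TRUE) + 1L
    pending[ready] <- FALSE
    if (!any(pending)) break
  }
  if (any(pending)) stop("pedigree contains a cycle (individual ",
                         id[which(pending)[1L]], ")")
  ord <- order(depth, seq_len(n))
  rank <- match(seq_len(n), ord)
  ped <- data.frame(id = id[ord],
                    sire = rank[si[ord]],
                    dam = rank[di[ord]],
                    generation = if (is.null(generation)) depth[ord]
                                 else as.integer(generation)[ord],
                    stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Read a pedigree CSV (id, sire, dam[, generation]); 0 = unknown parent
#' @param path CSV file path with a header row.
#' @return a \code{pedigree}.
#' @export
read_pedigree <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  pedigree(d$id, d$sire, d$dam,
           generation = if ("generation" %in% names(d)) d$generation else NULL)
}

#' Additive (numerator) relationship matrix from a pedigree
#'
#' Tabular (recursive) method:
#' \code{A[i,i] = 1 + 0.5 * A[sire, dam]} and
#' \code{A[i,j] = 0.5 * (A[j, sire(i)] + A[j, dam(i)])} for \code{j}
#' preceding \code{i}; unknown parents contribute 0.
#'
#' @param ped a \code{pedigree}.
#' @return symmetric PSD matrix with the pedigree's ids as dimnames.
#' @export
build_A <- function(ped) {
  n <- nrow(ped)
  A <- build_A_cpp(ifelse(is.na(ped$sire), 0L, ped$sire),
                   ifelse(is.na(ped$dam), 0L, ped$dam))
  dimnames(A) <- list(ped$id, ped$id)
  A
}

#' Mean inbreeding coefficient per generation
#' @param ped a \code{pedigree}.
#' @param A optional precomputed relationship matrix.
#' @return named numeric vector, mean \code{F = A[i,i] - 1} by generation.
#' @export
inbreeding_by_generation <- function(ped, A = build_A(ped)) {
  tapply(diag(A) - 1, ped$generation, mean)
}

#' Generate a random-mating pedigree
#'
#' Discrete generations: \code{n_founders} unrelated founders (half male,
#' half female), then \code{n_generations - 1} further generations of
#' \code{gen_size} individuals each, every one with a sire and dam drawn
#' uniformly from the males/females of the previous generation.
#'
#' @param n_founders number of founders (generation 1).
#' @param n_generations total generation count (1 = founders only).
#' @param gen_size individuals per non-founder generation; default
#'   \code{n_founders}.
#' @param seed integer RNG seed.
#' @return a \code{pedigree} with a logical \code{male} column attribute
#'   column retained in the data frame.
#' @export
generate_pedigree <- function(n_founders, n_generations, gen_size = n_founders,
                              seed = 1L) {
  stopifnot(n_founders >= 2, n_generations >= 1, gen_size >= 1)
  set.seed(seed)
  id <- paste0("G1_", seq_len(n_founders))
  sire <- rep(NA_character_, n_founders)
  dam <- rep(NA_character_, n_founders)
  gen <- rep(1L, n_founders)
  male <- rep(c(TRUE, FALSE), length.out = n_founders)
  prev <- id; prev_male <- male
  if (n_generations > 1) for (g in 2:n_generations) {
    males <- prev[prev_male]; females <- prev[!prev_male]
    nid <- paste0("G", g, "_", seq_len(gen_size))
    id <- c(id, nid)
    sire <- c(sire, sample(males, gen_size, replace = TRUE))
    dam <- c(dam, sample(females, gen_size, replace = TRUE))
    gen <- c(gen, rep(g, gen_size))
    nm <- rep(c(TRUE, FALSE), length.out = gen_size)
    male <- c(male, nm)
    prev <- nid; prev_male <- nm
  }
  ped <- pedigree(id, sire, dam, generation = gen)
  ped$male <- male[match(ped$id, id)]
  ped
}
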