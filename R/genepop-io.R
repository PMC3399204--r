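# GenePop dialect: title line; locus names one per line (or one comma-separated
# line); "POP"/"Pop"/"pop" separators; rows "id , 0102 0304 ...". Allele codes
# are fixed-width 2 or 3 digits per allele, 00/000 = missing.

newGenotypeMatrix <- function(individuals, loci, populations, a, b) {
  swap <- !is.na(a) & !is.na(b) & a > b
  if (any(swap)) {
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  }
  dimnames(a) <- dimnames(b) <- list(individuals, loci)
  new("GenotypeMatrix", individuals = individuals, loci = loci,
      populations = populations,
      alleleA = a, alleleB = b)
}

#' Read a GenePop-format genotype file
#'
#' Parses the GenePop text dialect: a title line, locus names (one per line or
#' a single comma-separated line), \code{POP} separators, and one row per
#' individual of the form \code{"id , 0102 0304 ..."}.  Two- and three-digit
#' allele encodings are auto-detected from token width; \code{00}/\code{000}
#' denotes a missing call.  Population labels default to the identifier of the
#' last individual in each block (the GenePop convention) unless
#' \code{popNames} overrides them.
#'
#' @param path path to the file.
#' @param popNames optional character vector naming the populations in file
#'   order (recycled errors are not allowed; length must match block count).
#' @return a [GenotypeMatrix-class].
#' @examples
#' f <- tempfile()
#' writeLines(c("toy", "locA", "locB", "POP",
#'              "ind1 , 0102 0303", "ind2 , 0101 0000"), f)
#' gm <- readGenepop(f, popNames = "demo")
#' nInd(gm)
#' @export
readGenepop <- function(path, popNames = NULL) {
  raw <- readLines(path, warn = FALSE)
  lines <- trimws(raw)
  keep <- nzchar(lines)
  lineNo <- seq_along(lines)[keep]
  lines <- lines[keep]
  if (length(lines) < 3)
    stop("GenePop parse error: file too short")
  isPop <- toupper(lines) == "POP"
  firstPop <- which(isPop)[1]
  if (is.na(firstPop))
    stop("GenePop parse error: no POP separator found")
  headerLines <- lines[2:(firstPop - 1)]
  if (length(headerLines) == 1 && grepl(",", headerLines)) {
    lociNames <- trimws(strsplit(headerLines, ",")[[1]])
  } else {
    lociNames <- headerLines
  }
  lociNames <- lociNames[nzchar(lociNames)]
  if (!length(lociNames))
    stop("GenePop parse error: no locus names before first POP")
  L <- length(lociNames)

  ids <- character(0); popIdx <- integer(0)
  rowsA <- list(); rowsB <- list()
  blockSizes <- integer(0)
  block <- 0L
  width <- NA_integer_
  for (k in seq(firstPop, length(lines))) {
    ln <- lines[k]
    if (toupper(ln) == "POP") {
      if (block > 0L && blockSizes[block] == 0L)
        stop(sprintf("GenePop parse error: empty POP block %d", block))
      block <- block + 1L
      blockSizes[block] <- 0L
      next
    }
    parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
    if (length(parts) < 2)
      stop(sprintf("GenePop parse error at line %d: missing ',' separator",
                   lineNo[k]))
    id <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = ",")),
                     "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) != L)
      stop(sprintf(
        "GenePop parse error at line %d: %d genotype tokens, expected %d",
        lineNo[k], length(toks), L))
    if (!all(grepl("^[0-9]+$", toks)))
      stop(sprintf("GenePop parse error at line %d: non-numeric genotype",
                   lineNo[k]))
    w <- unique(nchar(toks))
    if (length(w) != 1 || !(w %in% c(4L, 6L)))
      stop(sprintf(
        "GenePop parse error at line %d: genotype tokens must be 4 or 6 digits",
        lineNo[k]))
    w <- w %/% 2L
    if (is.na(width)) width <- w
    else if (width != w)
      stop(sprintf("GenePop parse error at line %d: mixed allele digit widths",
                   lineNo[k]))
    a <- as.integer(substr(toks, 1L, width))
    b <- as.integer(substr(toks, width + 1L, 2L * width))
    miss <- a == 0L | b == 0L
    a[miss] <- NA_integer_; b[miss] <- NA_integer_
    ids <- c(ids, id)
    popIdx <- c(popIdx, block)
    rowsA[[length(rowsA) + 1L]] <- a
    rowsB[[length(rowsB) + 1L]] <- b
    blockSizes[block] <- blockSizes[block] + 1L
  }
  if (block == 0L || !length(ids))
    stop("GenePop parse error: no individuals found")
  if (blockSizes[block] == 0L)
    stop(sprintf("GenePop parse error: empty POP block %d", block))
  if (is.null(popNames)) {
    last <- vapply(seq_len(block),
                   function(bk) ids[max(which(popIdx == bk))], character(1))
    popNames <- make.unique(last)
  } else if (length(popNames) != block) {
    stop(sprintf("popNames has length %d but file has %d POP blocks",
                 length(popNames), block))
  }
  newGenotypeMatrix(ids, lociNames, popNames[popIdx],
                    do.call(rbind, rowsA), do.call(rbind, rowsB))
}

#' Write a GenotypeMatrix as a GenePop file
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path output path.
#' @param digits allele digit width, 2 or 3 (default 3).
#' @param title title line content.
#' @return \code{path}, invisibly.
#' @export
writeGenepop <- function(gm, path, digits = 3L, title = "islandpop export") {
  stopifnot(is(gm, "GenotypeMatrix"))
  digits <- as.integer(digits)
  if (!digits %in% c(2L, 3L))
    stop("digits must be 2 or 3")
  maxAllele <- suppressWarnings(max(gm@alleleB, na.rm = TRUE))
  if (is.finite(maxAllele) && maxAllele >= 10^digits)
    stop(sprintf("allele label %d does not fit in %d digits",
                 maxAllele, digits))
  fmt <- function(x) {
    out <- formatC(x, width = digits, flag = "0")
    out[is.na(x)] <- strrep("0", digits)
    out
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(gm@loci, con)
  pops <- unique(gm@populations)
  for (p in pops) {
    writeLines("POP", con)
    for (i in which(gm@populations == p)) {
      toks <- paste0(fmt(gm@alleleA[i, ]), fmt(gm@alleleB[i, ]))
      writeLines(paste(gm@individuals[i], ",", paste(toks, collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Subset a GenotypeMatrix to one or more populations
#'
#' @param gm a [GenotypeMatrix-class].
#' @param pops population labels to keep, in the order given.
#' @return a [GenotypeMatrix-class] restricted to those individuals.
#' @export
subsetPopulations <- function(gm, pops) {
  unknown <- setdiff(pops, unique(gm@populations))
  if (length(unknown))
    stop("unknown population label(s): ", paste(unknown, collapse = ", "))
  idx <- which(gm@populations %in% pops)
  idx <- idx[order(match(gm@populations[idx], pops))]
  if (!length(idx)) stop("no individuals selected")
  newGenotypeMatrix(gm@individuals[idx], gm@loci, gm@populations[idx],
                    gm@alleleA[idx, , drop = FALSE],
                    gm@alleleB[idx, , drop = FALSE])
}
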