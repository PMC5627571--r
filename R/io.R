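## File formats: .geno haplotype matrices, VCF (via vcfR), ESRI ASCII
## grids, and deterministic fixture generation.

#' Read and write .geno haplotype matrices
#'
#' The `.geno` dialect stores one text line per locus with one character
#' per chromosome: `0` (ancestral/reference), `1` (derived) or `9`
#' (missing). `transpose = TRUE` reads/writes chromosomes as lines
#' instead.
#'
#' @param path file path.
#' @param chromosomeIds optional chromosome identifiers.
#' @param transpose treat lines as chromosomes rather than loci.
#' @param polarization passed to [HaplotypeMatrix()].
#' @return `readGeno` returns a [HaplotypeMatrix-class]; `writeGeno`
#'   returns `path` invisibly.
#' @export
readGeno <- function(path, chromosomeIds = NULL, transpose = FALSE,
                     polarization = "ancestral-known") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty .geno file: ", path)
  widths <- nchar(lines)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    stop("ragged .geno file: line ", bad, " has ", widths[bad],
         " characters, expected ", widths[1])
  }
  chars <- strsplit(lines, "")
  ok <- vapply(chars, function(ch) all(ch %in% c("0", "1", "9")), logical(1))
  if (!all(ok))
    stop("illegal character in .geno file at line ", which(!ok)[1])
  m <- do.call(rbind, lapply(chars, function(ch) {
    v <- as.integer(ch); v[v == 9L] <- NA_integer_; v
  }))
  if (transpose) m <- t(m)
  HaplotypeMatrix(m, chromosomeIds = chromosomeIds,
                  polarization = polarization)
}

#' @rdname readGeno
#' @param x a [HaplotypeMatrix-class].
#' @export
writeGeno <- function(x, path, transpose = FALSE) {
  a <- alleles(x)
  a[is.na(a)] <- 9L
  if (transpose) a <- t(a)
  writeLines(apply(a, 1, paste, collapse = ""), path)
  invisible(path)
}

#' Read a VCF into a HaplotypeMatrix
#'
#' Only biallelic SNP records are used (others are skipped, with counts
#' reported). Genotypes are haploidized per `policy`: `"haploid"` expects
#' single-allele GT fields; `"collapse"` maps homozygous diploid calls to
#' the allele and heterozygotes to missing; `"random"` takes one allele of
#' each diploid call at random (seeded).
#'
#' @param path VCF file (plain or gzipped).
#' @param policy haploidization policy.
#' @param seed RNG seed for `policy = "random"`.
#' @return a [HaplotypeMatrix-class] (loci x samples).
#' @export
readVcf <- function(path, policy = c("collapse", "haploid", "random"),
                    seed = NULL) {
  policy <- match.arg(policy)
  if (!is.null(seed)) set.seed(seed)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  nRec <- nrow(v@gt)
  if (nRec == 0L) stop("no records in VCF: ", path)
  keep <- vcfR::is.biallelic(v)
  nSkip <- sum(!keep)
  if (nSkip > 0)
    message("readVcf: skipped ", nSkip, " non-biallelic records")
  v <- v[keep, ]
  gt <- vcfR::extract.gt(v, element = "GT")
  conv <- function(g) {
    g[g %in% c(".", "./.", ".|.")] <- NA_character_
    out <- rep(NA_integer_, length(g))
    hap <- g %in% c("0", "1")
    out[hap] <- as.integer(g[hap])
    dip <- grepl("^[01][/|][01]$", g)
    if (any(dip)) {
      a1 <- as.integer(substr(g[dip], 1, 1))
      a2 <- as.integer(substr(g[dip], 3, 3))
      if (policy == "collapse") {
        out[dip] <- ifelse(a1 == a2, a1, NA_integer_)
      } else if (policy == "random") {
        pickFirst <- runif(sum(dip)) < 0.5
        out[dip] <- ifelse(pickFirst, a1, a2)
      } else {
        out[dip] <- NA_integer_
      }
    }
    out
  }
  m <- apply(gt, 2, conv)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  if (all(is.na(m))) stop("no usable genotype calls in VCF: ", path)
  HaplotypeMatrix(m, chromosomeIds = colnames(gt))
}

#' Read and write ESRI ASCII grids
#'
#' Standard `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header
#' followed by rows from north to south.
#'
#' @param path file path.
#' @return `readAsciiGrid` returns a list with `values` (matrix, row 1 =
#'   north), `lon`, `lat` (cell centers) and `nodata`.
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("missing ESRI ASCII header fields in ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("cell count does not match header in ", path)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  cs <- hdr$cellsize
  lon <- hdr$xllcorner + cs * (seq_len(hdr$ncols) - 0.5)
  lat <- hdr$yllcorner + cs * (hdr$nrows - seq_len(hdr$nrows) + 0.5)
  list(values = m, lon = lon, lat = lat, nodata = nodata)
}

#' @rdname readAsciiGrid
#' @param values matrix (row 1 = north); `NA` written as the nodata value.
#' @param lon,lat cell-center coordinates (lat decreasing).
#' @param nodata nodata sentinel.
#' @export
writeAsciiGrid <- function(values, lon, lat, path, nodata = -9999) {
  cs <- if (length(lon) > 1) mean(diff(lon)) else 1
  hdr <- c(
    paste("ncols", ncol(values)),
    paste("nrows", nrow(values)),
    paste("xllcorner", format(min(lon) - cs / 2, scientific = FALSE)),
    paste("yllcorner", format(min(lat) - cs / 2, scientific = FALSE)),
    paste("cellsize", format(cs, scientific = FALSE)),
    paste("NODATA_value", nodata))
  v <- values
  v[is.na(v)] <- nodata
  body <- apply(v, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Convert a capacity raster into a DemeGrid
#'
#' Cells with positive capacity become `"other"` land, non-positive or
#' `NA` cells become `"sea"`.
#'
#' @param raster a list as returned by [readAsciiGrid()].
#' @return a [DemeGrid-class].
#' @export
demeGridFromRaster <- function(raster) {
  cap <- raster$values
  cap[is.na(cap)] <- 0
  hab <- matrix("sea", nrow(cap), ncol(cap))
  hab[cap > 0] <- "other"
  DemeGrid(hab, raster$lon, raster$lat, capacity = cap)
}

# Ray-casting point-in-polygon (polygon as two-column matrix, closed
# implicitly). Sufficient for the coarse synthetic coastline below.
pointInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Synthetic Africa-like habitat grid
#'
#' An 87 x 83 deme lattice over a coarse, hand-drawn coastline polygon
#' loosely shaped like the African continent, with latitude-band
#' vegetation classes (extreme desert around 18-28 N, semi-desert in the
#' 12-18 N Sahel band, rain forest near the equator). This is a synthetic
#' stand-in for continental-scale runs, not a georeferenced map.
#'
#' @param nrows,ncols lattice dimensions.
#' @return a [DemeGrid-class] with habitat classes and all-land C = 100.
#' @export
africaLikeGrid <- function(nrows = 87L, ncols = 83L) {
  coast <- cbind(
    lon = c(-9, -5, 10, 20, 32, 34, 43, 51, 41, 40, 35, 32, 28, 19, 16,
            12, 9, 9, 13, 8, -5, -10, -17, -17, -12),
    lat = c(35, 36, 37, 33, 31, 28, 11, 12, -2, -11, -20, -29, -34, -35,
            -28, -18, -7, 0, 5, 4, 5, 4, 10, 20, 28))
  lon <- seq(-18, 52, length.out = ncols)
  lat <- seq(38, -36, length.out = nrows)
  px <- rep(lon, each = nrows)
  py <- rep(lat, ncols)
  land <- pointInPolygon(px, py, coast)
  hab <- matrix("sea", nrows, ncols)
  hab[matrix(land, nrows, ncols)] <- "other"
  latM <- matrix(py, nrows, ncols)
  lonM <- matrix(px, nrows, ncols)
  isLand <- hab != "sea"
  hab[isLand & latM > 18 & latM < 28] <- "extreme-desert"
  hab[isLand & latM >= 12 & latM <= 18] <- "semi-desert"
  hab[isLand & abs(latM - 2) < 6 & lonM > -14 & lonM < 30] <- "rain-forest"
  DemeGrid(hab, lon, lat)
}

#' Small demo habitat grid
#'
#' A 20 x 20 lattice with a one-cell sea border and a Sahel-like interior
#' (semi-desert band flanked by extreme desert to the north and rain
#' forest to the south), spanning the western part of the origin prior
#' box. Used by examples and small-scale studies.
#'
#' @return a [DemeGrid-class].
#' @export
demoGrid <- function() {
  hab <- matrix("other", 20, 20)
  hab[1, ] <- hab[20, ] <- hab[, 1] <- hab[, 20] <- "sea"
  lat <- seq(29, 6, length.out = 20)
  lon <- seq(-16, 12, length.out = 20)
  latM <- matrix(rep(lat, 20), 20, 20)
  inner <- hab != "sea"
  hab[inner & latM > 22] <- "extreme-desert"
  hab[inner & latM <= 22 & latM > 14] <- "semi-desert"
  hab[inner & latM <= 10] <- "rain-forest"
  DemeGrid(hab, lon, lat)
}

#' Generate the packaged fixture bundle
#'
#' Writes, deterministically from `seed`: the synthetic Africa-like
#' habitat raster (87 x 83), the 20 x 20 demo raster, a synthetic set of
#' 146 accession coordinates inside the Sahel prior box (lon -16..40,
#' lat 5..30), and a small demo `.geno` matrix.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed.
#' @return named character vector of the file paths written.
#' @export
makeFixtures <- function(outDir, seed = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  paths <- c(
    africa = file.path(outDir, "africa_like_synthetic.asc"),
    demo = file.path(outDir, "demo_grid.asc"),
    accessions = file.path(outDir, "synthetic_accessions.csv"),
    geno = file.path(outDir, "demo.geno"))
  af <- africaLikeGrid()
  af <- makeHabitatMap("vegetation", af)
  writeAsciiGrid(capacity(af), af@lon, af@lat, paths["africa"])
  dg <- demoGrid()
  writeAsciiGrid(capacity(dg), dg@lon, dg@lat, paths["demo"])
  n <- 146L
  lon <- numeric(0); lat <- numeric(0)
  af2 <- af
  while (length(lon) < n) {
    cl <- runif(2 * n, -16, 40)
    ca <- runif(2 * n, 5, 30)
    rc <- vapply(seq_along(cl), function(i) {
      p <- nearestCell(af2, cl[i], ca[i])
      capacity(af2)[p["row"], p["col"]] > 0
    }, logical(1))
    lon <- c(lon, cl[rc]); lat <- c(lat, ca[rc])
  }
  acc <- data.frame(id = paste0("acc", seq_len(n)),
                    lon = round(lon[seq_len(n)], 4),
                    lat = round(lat[seq_len(n)], 4))
  write.table(acc, paths["accessions"], sep = ",", row.names = FALSE,
              quote = FALSE)
  tr <- simulateNeutralGenealogy(10)
  g <- dropMutations(tr, 8)
  writeGeno(HaplotypeMatrix(t(g)), paths["geno"])
  paths
}
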