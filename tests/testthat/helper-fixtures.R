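# Shared fixtures and independent oracles, built in code at test time.

# hand-written fixed-column PDB lines for parser edge cases
writePDBLines <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

pdbAtomLine <- function(serial, name, resid, chain, resno, x, y, z,
                        occ = 1, alt = " ", element = "C") {
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resid, chain, resno, x, y, z, occ, 0, element)
}

# tiny structure with arbitrary CA placements (for distance arithmetic)
caStructure <- function(resno, xyz, resid = NULL, id = "fix") {
  if (is.null(resid)) resid <- rep("ALA", length(resno))
  lines <- vapply(seq_along(resno), function(i)
    pdbAtomLine(i, "CA ", resid[i], "A", resno[i],
                xyz[i, 1], xyz[i, 2], xyz[i, 3]), character(1))
  readStructure(writePDBLines(lines), structureId = id)
}

randomRotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# exhaustive-enumeration oracle for global alignment with affine gaps:
# walks every monotone alignment path and scores gap runs explicitly,
# independent of any dynamic-programming recurrence
enumerateAlignmentScore <- function(a, b, sm, gapOpen = 10,
                                    gapExtend = 0.5) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  best <- -Inf
  rec <- function(i, j, last, acc) {
    if (i > n && j > m) {
      if (acc > best) best <<- acc
      return(invisible(NULL))
    }
    if (i <= n && j <= m)
      rec(i + 1, j + 1, "M", acc + sm[A[i], B[j]])
    if (i <= n)
      rec(i + 1, j, "X",
          acc - (if (identical(last, "X")) gapExtend else
                   gapOpen + gapExtend))
    if (j <= m)
      rec(i, j + 1, "Y",
          acc - (if (identical(last, "Y")) gapExtend else
                   gapOpen + gapExtend))
  }
  rec(1, 1, "", 0)
  best
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

randomAASequence <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}
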