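# Session-level molecule cache: chemistry ingestion shells out to Open Babel
# (and RDKit for 3D), so repeated structures are parsed once.
.molcache <- new.env(parent = emptyenv())

mol <- function(smiles, name = smiles, embed3d = FALSE, seed = 1L) {
  key <- paste(smiles, embed3d, seed, sep = "\r")
  if (is.null(.molcache[[key]]))
    .molcache[[key]] <- parseSmiles(smiles, name = name, embed3d = embed3d,
                                    seed = seed)
  .molcache[[key]]
}

# Named group-count vector of a molecule (keys "backbone|neighbors").
gcounts <- function(m) groupCounts(fragmentMolecule(m))

# Minimal methane molfile (V2000), used for MOL/SDF reading tests.
methaneMolblock <- function() {
  paste(c("methane", "  test", "",
          "  5  4  0  0  0  0  0  0  0  0999 V2000",
          sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                  c(0, 0.63, -0.63, -0.63, 0.63),
                  c(0, 0.63, -0.63, 0.63, -0.63),
                  c(0, 0.63, 0.63, -0.63, -0.63),
                  c("C", "H", "H", "H", "H")),
          "  1  2  1  0  0  0  0", "  1  3  1  0  0  0  0",
          "  1  4  1  0  0  0  0", "  1  5  1  0  0  0  0",
          "M  END"), collapse = "\n")
}

# Write an SD file with optional data fields for a list of molblocks.
writeSDFile <- function(molblocks, fields = NULL, path = tempfile(fileext = ".sdf")) {
  out <- character()
  for (i in seq_along(molblocks)) {
    out <- c(out, molblocks[[i]])
    if (!is.null(fields) && length(fields[[i]])) {
      f <- fields[[i]]
      for (tag in names(f))
        out <- c(out, sprintf(">  <%s>", tag), as.character(f[[tag]]), "")
    }
    out <- c(out, "$$$$")
  }
  writeLines(out, path)
  path
}
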