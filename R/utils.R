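# internal helpers shared across the package

# round half away from zero (the convention used by the printed tables;
# base round() is half-to-even)
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# read a packaged TSV whose leading '#' comment lines carry metadata
# (e.g. "# version: 2026.1"); metadata is attached as attributes
read_reference_tsv <- function(path) {
  header <- readLines(path, n = 20L)
  meta_lines <- grep("^#", header, value = TRUE)
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z0-9_]+)\\s*:\\s*(.+)$", ln))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- trimws(m[3])
  }
  for (nm in names(meta)) attr(tab, nm) <- meta[[nm]]
  tab
}

kirscreen_extdata <- function(file) {
  path <- system.file("extdata", file, package = "kirscreen")
  if (!nzchar(path)) {
    # during development (pkgload) system.file resolves; guard anyway
    rlang::abort(paste0("packaged reference file not found: ", file))
  }
  path
}
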