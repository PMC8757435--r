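## Extended-XYZ reader/writer, pinned to the widely used Lattice/Properties
## comment-line convention: per-frame key=value fields (quoted values may
## contain spaces), a Properties string such as
## species:S:1:pos:R:3:forces:R:3, energies under the key "energy" (eV),
## positions and forces in Angstrom / eV Angstrom^-1. Unknown per-atom
## columns survive a read/write round trip verbatim.

parse_keyvals <- function(line) {
  out <- list()
  pat <- '([A-Za-z0-9_:+-]+)=("([^"]*)"|\\S+)'
  m <- gregexpr(pat, line, perl = TRUE)[[1]]
  if (m[1] == -1L) return(out)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  for (k in seq_along(starts)) {
    tok <- substr(line, starts[k], starts[k] + lens[k] - 1L)
    eq <- regexpr("=", tok, fixed = TRUE)
    key <- substr(tok, 1L, eq - 1L)
    val <- substr(tok, eq + 1L, nchar(tok))
    if (startsWith(val, '"')) val <- substr(val, 2L, nchar(val) - 1L)
    out[[key]] <- val
  }
  out
}

parse_properties <- function(str) {
  parts <- strsplit(str, ":", fixed = TRUE)[[1]]
  if (length(parts) %% 3L != 0L) stop("malformed Properties string: ", str)
  n <- length(parts) / 3L
  data.frame(name = parts[seq(1L, by = 3L, length.out = n)],
             type = parts[seq(2L, by = 3L, length.out = n)],
             ncol = as.integer(parts[seq(3L, by = 3L, length.out = n)]),
             stringsAsFactors = FALSE)
}

#' Read an extended-XYZ file
#'
#' Parses one or more frames into a [labeled_dataset()]. Frames without an
#' `energy` field or without force columns simply lack those entries (their
#' absence is visible as `NULL`). Per-atom columns other than species,
#' positions and forces are preserved under `extra`.
#'
#' @param path Path to the file.
#' @return A [labeled_dataset()].
#' @export
read_extxyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  ln <- 1L
  while (ln <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[ln])) {
      if (grepl("^\\s*$", lines[ln])) { ln <- ln + 1L; next }
      stop("parse error at line ", ln, ": expected an atom count")
    }
    nat <- as.integer(trimws(lines[ln]))
    if (ln + 1L + nat > length(lines)) {
      stop("parse error at line ", ln, ": truncated frame")
    }
    kv <- parse_keyvals(lines[ln + 1L])
    props <- parse_properties(kv$Properties %||% "species:S:1:pos:R:3")
    body <- lines[(ln + 2L):(ln + 1L + nat)]
    toks <- strsplit(trimws(body), "\\s+")
    want <- sum(props$ncol)
    bad <- which(lengths(toks) != want)
    if (length(bad)) {
      stop("parse error at line ", ln + 1L + bad[1L], ": expected ", want,
           " columns")
    }
    tab <- matrix(unlist(toks), nrow = nat, byrow = TRUE)
    col0 <- 0L
    species <- NULL; pos <- NULL; forc <- NULL; extra <- list()
    for (q in seq_len(nrow(props))) {
      cols <- col0 + seq_len(props$ncol[q])
      block <- tab[, cols, drop = FALSE]
      if (props$type[q] %in% c("R", "I")) {
        block <- matrix(as.numeric(block), nrow = nat)
      }
      switch(props$name[q],
             species = { species <- block[, 1L] },
             pos = { pos <- block },
             forces = { forc <- block },
             { extra[[props$name[q]]] <- block })
      col0 <- col0 + props$ncol[q]
    }
    if (is.null(species) || is.null(pos)) {
      stop("parse error at line ", ln + 1L, ": Properties must include ",
           "species and pos")
    }
    cell <- NULL
    periodic <- FALSE
    if (!is.null(kv$Lattice)) {
      cv <- as.numeric(strsplit(trimws(kv$Lattice), "\\s+")[[1]])
      if (length(cv) != 9L) stop("parse error at line ", ln + 1L,
                                 ": Lattice needs 9 numbers")
      cell <- matrix(cv, 3L, 3L, byrow = TRUE)
      periodic <- c(TRUE, TRUE, TRUE)
      if (!is.null(kv$pbc)) {
        periodic <- toupper(strsplit(trimws(kv$pbc), "\\s+")[[1]]) %in%
          c("T", "TRUE", "1")
      }
    }
    fr <- list(config = atomic_configuration(pos, species, cell, periodic))
    if (!is.null(kv$energy)) fr$energy <- as.numeric(kv$energy)
    if (!is.null(forc)) fr$forces <- forc
    if (length(extra)) fr$extra <- extra
    frames[[length(frames) + 1L]] <- fr
    ln <- ln + 2L + nat
  }
  labeled_dataset(frames)
}

fmt_num <- function(x) trimws(formatC(x, format = "g", digits = 17))

#' Write a dataset (or single configuration) as extended XYZ
#'
#' @param ds A [labeled_dataset()], a single frame list, or an
#'   [atomic_configuration()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_extxyz <- function(ds, path) {
  if (inherits(ds, "atomic_configuration")) ds <- list(list(config = ds))
  if (!is.null(ds$config)) ds <- list(ds)
  out <- character(0)
  for (fr in ds) {
    cfg <- fr$config
    nat <- n_atoms(cfg)
    fields <- character(0)
    if (!is.null(cfg$cell)) {
      fields <- c(fields, paste0('Lattice="',
                                 paste(fmt_num(as.numeric(t(cfg$cell))),
                                       collapse = " "), '"'))
      fields <- c(fields, paste0('pbc="',
                                 paste(ifelse(cfg$periodic, "T", "F"),
                                       collapse = " "), '"'))
    }
    props <- "species:S:1:pos:R:3"
    cols <- list(cfg$species, apply(cfg$positions, 1L, fmt_num))
    if (!is.null(fr$forces)) {
      props <- paste0(props, ":forces:R:3")
      cols <- c(cols, list(apply(fr$forces, 1L, fmt_num)))
    }
    for (nm in names(fr$extra %||% list())) {
      blk <- fr$extra[[nm]]
      tp <- if (is.numeric(blk)) "R" else "S"
      props <- paste0(props, ":", nm, ":", tp, ":", ncol(blk))
      cols <- c(cols, list(apply(blk, 1L,
                                 function(r) if (is.numeric(r)) fmt_num(r)
                                 else as.character(r))))
    }
    fields <- c(fields, paste0("Properties=", props))
    if (!is.null(fr$energy)) {
      fields <- c(fields, paste0("energy=", fmt_num(fr$energy)))
    }
    body <- vapply(seq_len(nat), function(i) {
      paste(vapply(cols, function(cl) {
        v <- if (is.matrix(cl)) cl[, i] else cl[i]
        paste(v, collapse = " ")
      }, character(1)), collapse = " ")
    }, character(1))
    out <- c(out, as.character(nat), paste(fields, collapse = " "), body)
  }
  writeLines(out, path)
  invisible(path)
}
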