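#' Write / read an anisotropic dataset as a plain-text directory
#'
#' The native on-disk layout is a self-describing directory of TSV
#' matrices plus JSON metadata: `meta.json` (solvent, dimensions, units),
#' `q.tsv`, `t.tsv`, and the `nq x nt` matrices `dS0.tsv`, `dS2.tsv`,
#' `err0.tsv`, `err2.tsv`. All numbers are written with full double
#' precision, so a write-read roundtrip is lossless to ~1e-15 relative.
#'
#' @param dataset An `aniso_dataset`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "aniso_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(solvent = dataset$solvent, n_q = length(dataset$q),
         n_t = length(dataset$t),
         units = list(q = "1/Angstrom", t = "ps",
                      dS = "electron units / solute molecule")),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  wr <- function(x, f) {
    utils::write.table(format(x, digits = 17, scientific = TRUE, trim = TRUE),
                       file.path(path, f), sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  wr(dataset$q, "q.tsv"); wr(dataset$t, "t.tsv")
  for (nm in c("dS0", "dS2", "err0", "err2")) wr(dataset[[nm]], paste0(nm, ".tsv"))
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  need <- c("meta.json", "q.tsv", "t.tsv", "dS0.tsv", "dS2.tsv", "err0.tsv",
            "err2.tsv")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing) > 0) {
    rlang::abort(paste0("Malformed dataset directory; missing: ",
                        paste(missing, collapse = ", ")))
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"))
  rd <- function(f) as.matrix(utils::read.table(file.path(path, f), sep = "\t"))
  q <- as.numeric(rd("q.tsv")); t <- as.numeric(rd("t.tsv"))
  m <- lapply(c("dS0", "dS2", "err0", "err2"), function(nm) {
    x <- rd(paste0(nm, ".tsv")); dimnames(x) <- NULL; x
  })
  names(m) <- c("dS0", "dS2", "err0", "err2")
  structure(c(list(q = q, t = t), m,
              list(solvent = meta$solvent, truth = NULL)),
            class = "aniso_dataset")
}

#' Two-column text curve export / import
#'
#' Writes a `(q, value)` curve as plain text with `#` header comments
#' (units documented in the header), readable by any plotting tool and by
#' [read_curve()].
#'
#' @param q,value Curve on a q grid.
#' @param path Output file.
#' @param comment Extra header line.
#' @return `path` (write) or a tibble with `q`, `value` (read).
#' @export
write_curve <- function(q, value, path, comment = "") {
  stopifnot(length(q) == length(value))
  hdr <- c("# trixs curve export", "# q [1/Angstrom]\tvalue [e.u./molecule]",
           if (nzchar(comment)) paste0("# ", comment))
  writeLines(c(hdr, sprintf("%.12g\t%.12g", q, value)), path)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  x <- utils::read.table(path, comment.char = "#", sep = "\t",
                         col.names = c("q", "value"))
  tibble::as_tibble(x)
}

#' Report a refinement + kinetics run to disk
#'
#' Writes the standard result set into a directory: the refined parameter
#' trajectories (`parameters.csv` and `parameters.png`, linear time axis
#' to 1 ps and logarithmic beyond), data-versus-model panels at selected
#' timepoints (`fit_panels.png`) and the kinetics table (`kinetics.csv`
#' plus a Markdown rendering `kinetics.md`).
#'
#' @param refinement A `txs_refinement`.
#' @param kinetics A `txs_kinetics` row from [kinetics_summary()].
#' @param path Output directory.
#' @param dataset Optional `aniso_dataset` for the data-model panels.
#' @param ctx Optional [forward_context()] for the data-model panels.
#' @param panel_times Timepoints (ps) shown in the fit panels.
#' @return `path`, invisibly.
#' @export
report <- function(refinement, kinetics, path, dataset = NULL, ctx = NULL,
                   panel_times = c(0.2, 0.5, 1, 10, 100)) {
  stopifnot(inherits(refinement, "txs_refinement"))
  if (nrow(refinement$params) == 0) rlang::abort("Empty refinement result; nothing to report.")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(refinement$params, file.path(path, "parameters.csv"))
  readr::write_csv(as.data.frame(kinetics), file.path(path, "kinetics.csv"))
  km <- as.data.frame(kinetics)
  md <- c("| quantity | value |", "| --- | --- |",
          sprintf("| %s | %.4g |", names(km), as.numeric(km[1, ])))
  writeLines(md, file.path(path, "kinetics.md"))
  p <- autoplot(refinement)
  ggplot2::ggsave(file.path(path, "parameters.png"), p, width = 8, height = 6,
                  dpi = 120)
  if (!is.null(dataset) && !is.null(ctx)) {
    pf <- plot_fit_panels(dataset, refinement, ctx, panel_times)
    ggplot2::ggsave(file.path(path, "fit_panels.png"), pf, width = 8,
                    height = 6, dpi = 120)
  }
  invisible(path)
}
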