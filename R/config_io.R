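#' Write / read a simulation config as a structured text file
#'
#' YAML serialisation of a [sim_config()]; reading applies the stored
#' values on top of the defaults, so files written by older versions with
#' fewer fields stay valid.
#'
#' @param config a `sim_config`.
#' @param path file path.
#' @return `read_sim_config` returns a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  cfg <- sim_config()
  if (!is.null(vals$size_model)) {
    for (nm in names(vals$size_model)) {
      v <- unlist(vals$size_model[[nm]])
      if (!is.null(cfg$size_model[[nm]]) && is.null(names(v)) &&
          length(v) == length(cfg$size_model[[nm]]))
        names(v) <- names(cfg$size_model[[nm]])
      cfg$size_model[[nm]] <- v
    }
    vals$size_model <- NULL
  }
  for (nm in intersect(names(vals), setdiff(names(cfg), "size_model"))) {
    v <- vals[[nm]]
    if (is.list(v) && nm != "introns_per_gene") v <- unlist(v)
    cfg[[nm]] <- v
  }
  for (nm in c("n_species", "n_families", "floor_bp", "retained_floor_bp",
               "element_len_bp", "n_terms", "planted_terms", "term_size",
               "spacer_bp", "seed"))
    cfg[[nm]] <- as.integer(cfg[[nm]])
  cfg$exon_len_range <- as.integer(unlist(cfg$exon_len_range))
  class(cfg) <- "sim_config"
  cfg
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param dm a `k2p_dist` or symmetric matrix.
#' @param path output path.
#' @export
write_phylip <- function(dm, path) {
  m <- if (inherits(dm, "k2p_dist")) dm$d else as.matrix(dm)
  con <- file(path, "wb")
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(formatC(rownames(m)[i], width = -10),
                       formatC(m[i, ], format = "f", digits = 6)),
                     collapse = "  "), con)
  close(con)
  invisible(path)
}
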