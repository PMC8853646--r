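#' Save a network to a directory of delimited text files
#'
#' Writes the manifest (JSON), the glomerulus, mitral-cell, granule-cell
#' and synapse tables (tab-separated, full double precision) so that a
#' save/load/save cycle is byte-identical.
#'
#' @param net a `bulb_network`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  man <- list(format = "bulbnet-network", version = 1L,
              mode = net$mode, p_connect = net$p_connect,
              gc_per_mc = net$gc_per_mc,
              eps = net$eps, consts = net$consts,
              n_discarded = net$n_discarded, n_drawn = net$n_drawn,
              space = list(radius = net$space$radius,
                           area_mm2 = net$space$area_mm2,
                           boundary = net$space$boundary,
                           box = net$space$box,
                           layers = unclass(net$space$layers)))
  writeLines(jsonlite::toJSON(man, auto_unbox = TRUE, digits = NA),
             file.path(path, "manifest.json"))
  wt <- function(df, f) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
    utils::write.table(df, file.path(path, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(net$space$glomeruli, "glomeruli.tsv")
  wt(net$mc, "mitral_cells.tsv")
  wt(net$gc, "granule_cells.tsv")
  wt(net$syn, "synapses.tsv")
  invisible(path)
}

#' Load a network saved by [save_network()]
#'
#' @param path directory written by [save_network()].
#' @return a `bulb_network`.
#' @export
load_network <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("not a network directory: missing manifest")
  man <- jsonlite::fromJSON(readLines(mf))
  if (!identical(man$format, "bulbnet-network"))
    stop("corrupt or foreign manifest")
  if (man$version != 1L) stop("unsupported network file version")
  rd <- function(f) {
    utils::read.table(file.path(path, f), sep = "\t", header = TRUE)
  }
  ls <- man$space$layers
  space <- structure(list(
    radius = man$space$radius, area_mm2 = man$space$area_mm2,
    layers = structure(ls[c("epl", "mcl", "ipl", "total", "epl_floor")],
                       class = "layer_stack"),
    boundary = man$space$boundary, box = man$space$box,
    glomeruli = rd("glomeruli.tsv")), class = "ob_space")
  structure(list(space = space, mc = rd("mitral_cells.tsv"),
                 gc = rd("granule_cells.tsv"), syn = rd("synapses.tsv"),
                 mode = man$mode, p_connect = man$p_connect,
                 gc_per_mc = man$gc_per_mc,
                 consts = man$consts, eps = man$eps,
                 n_discarded = man$n_discarded, n_drawn = man$n_drawn),
            class = "bulb_network")
}

#' Build a preset network fixture
#'
#' `tiny` (radius 150 um, 5 GCs per MC) builds in seconds and is meant
#' for tests; `small` (radius 300 um, 15 per MC) is a mid-size network;
#' `paper` (radius 600 um, 15 per MC) targets the full printed
#' configuration (about 3,550 MCs and 53,250 GCs).
#'
#' @param scale `"tiny"`, `"small"` or `"paper"`.
#' @param seed RNG seed; the same seed reproduces the fixture exactly.
#' @param ... passed to [generate_network()].
#' @return a `bulb_network`.
#' @export
make_fixture <- function(scale = c("tiny", "small", "paper"), seed = 1, ...) {
  scale <- match.arg(scale)
  cfg <- switch(scale,
                tiny = list(radius = 150, ratio = 5),
                small = list(radius = 300, ratio = 15),
                paper = list(radius = 600, ratio = 15))
  set.seed(seed)
  space <- build_space(cfg$radius)
  mcs <- place_mitral_cells(space)
  generate_network(space, mcs, gc_per_mc = cfg$ratio, ...)
}
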