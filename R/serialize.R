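# JSON serialization of genotypes, path codes and architecture specs.

#' Write a cell genotype to JSON
#'
#' @param genotype A [cell_genotype()].
#' @param file Output path.
#' @export
write_genotype_json <- function(genotype, file) {
  stopifnot(inherits(genotype, "cell_genotype"))
  conns <- function(cc) lapply(cc, function(cn) list(cn[[1]], cn[[2]]))
  jsonlite::write_json(list(normal = conns(genotype$normal),
                            reduce = conns(genotype$reduce),
                            nodes = genotype$nodes),
                       file, auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}

#' Read a cell genotype from JSON
#'
#' @param file Path written by [write_genotype_json()].
#' @return A [cell_genotype()].
#' @export
read_genotype_json <- function(file) {
  j <- jsonlite::read_json(file)
  conns <- function(cc) lapply(cc, function(cn)
    list(as.character(cn[[1]]), as.integer(cn[[2]])))
  cell_genotype(conns(j$normal), conns(j$reduce), as.integer(j$nodes))
}

#' Write a path code to JSON
#'
#' @param path A [path_code()].
#' @param file Output path.
#' @param width_mult Width multiplier recorded alongside the choices.
#' @export
write_path_json <- function(path, file, width_mult = 1) {
  stopifnot(inherits(path, "path_code"))
  jsonlite::write_json(list(choices = path$choices, width_mult = width_mult),
                       file, auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}

#' Read a path code from JSON
#'
#' @param file Path written by [write_path_json()].
#' @return List with `path` (a [path_code()]) and `width_mult`.
#' @export
read_path_json <- function(file) {
  j <- jsonlite::read_json(file)
  ch <- vapply(j$choices, as.integer, integer(1))
  list(path = path_code(ch, length(ch)),
       width_mult = if (is.null(j$width_mult)) 1 else as.numeric(j$width_mult))
}

block_to_list <- function(b) unclass(b)

block_from_list <- function(l) {
  block_spec(l$kind, l$cin, l$cout, l$stride, l$expand, as.integer(l$kernel),
             isTRUE(l$use_se),
             if (is.null(l$se_reduction)) 4L else as.integer(l$se_reduction),
             force_expand = isTRUE(l$force_expand))
}

#' Write an architecture specification to JSON
#'
#' @param arch An [arch_spec()].
#' @param file Output path.
#' @export
write_arch_json <- function(arch, file) {
  stopifnot(inherits(arch, "arch_spec"))
  out <- list(name = arch$name, input_channels = arch$input_channels,
              stem = arch$stem, head = arch$head)
  if (!is.null(arch$blocks)) out$blocks <- lapply(arch$blocks, block_to_list)
  if (!is.null(arch$cells)) {
    cc <- arch$cells
    out$cells <- list(
      genotype = list(
        normal = lapply(cc$genotype$normal, function(cn) list(cn[[1]], cn[[2]])),
        reduce = lapply(cc$genotype$reduce, function(cn) list(cn[[1]], cn[[2]])),
        nodes = cc$genotype$nodes),
      init_channels = cc$init_channels, num_cells = cc$num_cells,
      reduction_positions = cc$reduction_positions, num_nodes = cc$num_nodes)
  }
  jsonlite::write_json(out, file, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(file)
}

#' Read an architecture specification from JSON
#'
#' @param file Path written by [write_arch_json()].
#' @return An [arch_spec()].
#' @export
read_arch_json <- function(file) {
  j <- jsonlite::read_json(file)
  blocks <- if (!is.null(j$blocks)) lapply(j$blocks, block_from_list)
  cells <- if (!is.null(j$cells)) {
    conns <- function(cc) lapply(cc, function(cn)
      list(as.character(cn[[1]]), as.integer(cn[[2]])))
    list(genotype = cell_genotype(conns(j$cells$genotype$normal),
                                  conns(j$cells$genotype$reduce),
                                  as.integer(j$cells$genotype$nodes)),
         init_channels = as.integer(j$cells$init_channels),
         num_cells = as.integer(j$cells$num_cells),
         reduction_positions = vapply(j$cells$reduction_positions, as.integer,
                                      integer(1)),
         num_nodes = as.integer(j$cells$num_nodes))
  }
  head <- j$head
  head$num_classes <- as.integer(head$num_classes)
  arch_spec(j$name,
            stem = list(cout = as.integer(j$stem$cout),
                        kernel = as.integer(j$stem$kernel),
                        stride = as.integer(j$stem$stride)),
            blocks = blocks, cells = cells, head = head,
            input_channels = as.integer(j$input_channels))
}

#' Write a complexity report to JSON
#'
#' @param report A `complexity_report` from [count_network()].
#' @param file Output path.
#' @param units `"raw"` (operation counts), `"G"` (FLOPs in 1e9 and params
#'   in 1e6) or `"M"` (both in 1e6).
#' @export
write_complexity_json <- function(report, file, units = c("G", "raw", "M")) {
  units <- match.arg(units)
  vals <- switch(units,
    raw = list(flops = report$flops, params = report$params),
    G = list(flops_g = report$flops_g, params_m = report$params_m),
    M = list(flops_m = report$flops / 1e6, params_m = report$params_m))
  jsonlite::write_json(c(vals, list(depth = report$depth,
                                    input_hw = report$input_hw,
                                    convention = report$convention)),
                       file, auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}

#' Write an evaluation report to JSON
#'
#' @param report An `eval_report` from [evaluate_ages()].
#' @param file Output path.
#' @export
write_eval_json <- function(report, file) {
  jsonlite::write_json(list(mae = report$mae,
                            cs_curve = as.list(report$cs_curve),
                            per_bin_mae = as.list(report$per_bin_mae),
                            n = report$n),
                       file, auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}
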