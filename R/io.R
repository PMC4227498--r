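## Standard-format I/O: VTK legacy ASCII unstructured grids (read/write,
## region labels as cell data "region"), Gmsh MSH v2 ASCII (write), and
## channel time histories as CSV with a units header row.

#' Write a mesh as a VTK legacy unstructured grid
#'
#' ASCII legacy format; region labels are written as integer cell data
#' `region` with the label dictionary in the header comment line.
#'
#' @param mesh a `head_mesh`.
#' @param path output file (conventionally `.vtk`).
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  regs <- sort(unique(mesh$region))
  writeLines(c("# vtk DataFile Version 3.0",
               paste("headfem mesh; regions:", paste(regs, collapse = ",")),
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", nrow(mesh$nodes), "double")), con)
  utils::write.table(format(mesh$nodes, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  m <- nrow(mesh$elems)
  writeLines(paste("CELLS", m, 5 * m), con)
  utils::write.table(cbind(4L, mesh$elems - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(paste("CELL_TYPES", m), con)
  writeLines(as.character(rep(10L, m)), con)   # VTK_TETRA
  writeLines(c(paste("CELL_DATA", m), "SCALARS region int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(match(mesh$region, regs) - 1L), con)
  invisible(path)
}

#' Read a VTK legacy unstructured tetrahedral grid
#'
#' Reads meshes written by [write_mesh_vtk()] (ASCII legacy, tetrahedra
#' only, optional `region` cell data).
#'
#' @param path input file.
#' @return a `head_mesh`.
#' @export
read_mesh_vtk <- function(path) {
  lines <- readLines(path)
  regs <- NULL
  hdr <- grep("regions:", lines, value = TRUE)
  if (length(hdr))
    regs <- strsplit(sub(".*regions:\\s*", "", hdr[1]), ",")[[1]]
  ip <- grep("^POINTS", lines)[1]
  npt <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  pts <- scan(text = lines[(ip + 1):(ip + npt)], quiet = TRUE)
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  m <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cel <- scan(text = lines[(ic + 1):(ic + m)], quiet = TRUE)
  cel <- matrix(cel, ncol = 5, byrow = TRUE)
  if (any(cel[, 1] != 4)) stop("only tetrahedral cells supported")
  elems <- cel[, 2:5] + 1L
  region <- "body"
  ir <- grep("^SCALARS region", lines)
  if (length(ir)) {
    rid <- scan(text = lines[(ir[1] + 2):(ir[1] + 1 + m)], quiet = TRUE)
    region <- if (!is.null(regs)) regs[rid + 1] else as.character(rid)
  }
  head_mesh(nodes, elems, region)
}

#' Write a mesh in Gmsh MSH v2 ASCII format
#'
#' Tetrahedra (element type 4) with the region label index as the
#' physical tag.
#'
#' @param mesh a `head_mesh`.
#' @param path output file (conventionally `.msh`).
#' @return `path`, invisibly.
#' @export
write_mesh_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  regs <- sort(unique(mesh$region))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nrow(mesh$nodes))), con)
  utils::write.table(cbind(seq_len(nrow(mesh$nodes)),
                           format(mesh$nodes, digits = 17, trim = TRUE)),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(c("$EndNodes", "$Elements", as.character(nrow(mesh$elems))), con)
  tag <- match(mesh$region, regs)
  utils::write.table(cbind(seq_len(nrow(mesh$elems)), 4L, 2L, tag, tag,
                           mesh$elems),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Write channel time histories as CSV
#'
#' First row: channel names; second row: units; data rows follow.
#'
#' @param history an `impact_history` (or plain data frame).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_history_csv <- function(history, path) {
  ch <- if (inherits(history, "impact_history")) history$channels else history
  units <- if (inherits(history, "impact_history"))
    history$units[names(ch)] else rep("-", ncol(ch))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(ch), collapse = ","), con)
  writeLines(paste(ifelse(is.na(units), "-", units), collapse = ","), con)
  utils::write.table(format(ch, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read channel time histories written by [write_history_csv()]
#' @param path input file.
#' @return data frame of channels with a `units` attribute.
#' @export
read_history_csv <- function(path) {
  hdr <- readLines(path, n = 2L)
  nms <- strsplit(hdr[1], ",")[[1]]
  units <- strsplit(hdr[2], ",")[[1]]
  df <- utils::read.csv(path, skip = 2L, header = FALSE,
                        col.names = nms, check.names = FALSE)
  attr(df, "units") <- setNames(units, nms)
  df
}

#' Write a per-element scalar field beside a mesh as VTK
#'
#' @param mesh a `head_mesh`.
#' @param field numeric per-element values.
#' @param name field name.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_field_vtk <- function(mesh, field, name, path) {
  write_mesh_vtk(mesh, path)
  con <- file(path, "a")
  on.exit(close(con))
  writeLines(c(paste("SCALARS", name, "double 1"), "LOOKUP_TABLE default"), con)
  writeLines(format(field, digits = 17, trim = TRUE, scientific = TRUE), con)
  invisible(path)
}
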