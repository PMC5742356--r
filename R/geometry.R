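# Amplicon coordinate map.  One full-length insert reads, 5' to 3' on the
# forward strand:
#
#   [fwd primer][5' vector flank][VH|linker|VL (the scFv)][3' vector flank][rev primer rc]
#
# All spans are 1-based inclusive.  The "core" span is the interval retained
# when declaring a read identical to a reference while ignoring artifacts at
# and near the primer termini; by default it starts at position 3 and stops
# 36 nt short of the 3' end, which reproduces the published 939-bp core of a
# 977-bp insert.

#' Default PCR primers of the phagemid amplicon
#'
#' 23-mer forward and 20-mer reverse primer; the 3' end of the insert carries
#' the reverse complement of the reverse primer.
#' @name primers
#' @export
FWD_PRIMER <- "TGCAAATTCTATTTCAAGGAGAC"

#' @rdname primers
#' @export
REV_PRIMER <- "TCACGTGCAAAAGCAGCGGC"

# 53-nt linker: EcoRI site + Gly/Ser-rich spacer + XbaI site
#' Default 53-nt scFv linker containing EcoRI (GAATTC) and XbaI (TCTAGA) sites
#' @export
DEFAULT_LINKER <- paste0("GAATTC",
                         "GGTGGAGGCGGTTCAGGCGGAGGTGGCTCTGGCGGTGGCGG",
                         "TCTAGA")

# flank widths chosen so a 767-nt scFv yields a 977-nt amplicon, matching
# primer placements 96-74 nt upstream and 95-114 nt downstream of the insert
FIVE_FLANK_LEN <- 74L
THREE_FLANK_LEN <- 93L

#' Build the coordinate map of one scFv amplicon
#'
#' @param vh_len,vl_len domain lengths in nt.
#' @param linker_len linker length (default 53).
#' @param fwd_primer_len,rev_primer_len primer lengths.
#' @param five_flank_len,three_flank_len vector flank lengths.
#' @param core_start first core position (default 3).
#' @param core_trim3 nt excluded from the 3' end of the core (default 36,
#'   i.e. the reverse primer plus a 16-nt vicinity window).
#' @return an object of class `insert_geometry`: named list of 1-based
#'   inclusive spans (`fwd_primer_span`, `five_flank_span`, `scfv_span`,
#'   `vh_span`, `linker_span`, `vl_span`, `three_flank_span`,
#'   `rev_primer_span`, `core_span`) plus `total_len`.  `vh_span`/`vl_span`
#'   name the 5'-most and 3'-most domain slots; in a VL-VH or off-type layout
#'   they still delimit domain 1 and domain 2.
#' @export
insert_geometry <- function(vh_len = 351L, vl_len = 363L, linker_len = 53L,
                            fwd_primer_len = nchar(FWD_PRIMER),
                            rev_primer_len = nchar(REV_PRIMER),
                            five_flank_len = FIVE_FLANK_LEN,
                            three_flank_len = THREE_FLANK_LEN,
                            core_start = 3L, core_trim3 = 36L) {
  widths <- c(fwd_primer_len, five_flank_len, vh_len, linker_len, vl_len,
              three_flank_len, rev_primer_len)
  stopifnot(all(widths > 0))
  ends <- cumsum(widths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  total <- ends[length(ends)]
  g <- list(
    total_len = as.integer(total),
    fwd_primer_span = iv(starts[1], ends[1]),
    five_flank_span = iv(starts[2], ends[2]),
    scfv_span = iv(starts[3], ends[5]),
    vh_span = iv(starts[3], ends[3]),
    linker_span = iv(starts[4], ends[4]),
    vl_span = iv(starts[5], ends[5]),
    three_flank_span = iv(starts[6], ends[6]),
    rev_primer_span = iv(starts[7], ends[7]),
    core_span = iv(core_start, total - core_trim3))
  class(g) <- "insert_geometry"
  validate_geometry(g)
}

validate_geometry <- function(g) {
  spans <- list(g$fwd_primer_span, g$five_flank_span, g$scfv_span,
                g$three_flank_span, g$rev_primer_span)
  starts <- vapply(spans, `[[`, 1L, "start")
  ends <- vapply(spans, `[[`, 1L, "end")
  if (starts[1] != 1L || ends[5] != g$total_len ||
      any(starts[-1] != ends[-5] + 1L))
    stop("geometry spans must tile [1, total_len] in order", call. = FALSE)
  inner <- list(g$vh_span, g$linker_span, g$vl_span)
  istarts <- vapply(inner, `[[`, 1L, "start")
  iends <- vapply(inner, `[[`, 1L, "end")
  if (istarts[1] != g$scfv_span[["start"]] || iends[3] != g$scfv_span[["end"]] ||
      any(istarts[-1] != iends[-3] + 1L))
    stop("vh/linker/vl spans must tile the scfv span", call. = FALSE)
  if (g$core_span[["start"]] < 1L || g$core_span[["end"]] > g$total_len ||
      g$core_span[["start"]] > g$core_span[["end"]])
    stop("core_span must be a sub-interval of [1, total_len]", call. = FALSE)
  g
}

#' @export
print.insert_geometry <- function(x, ...) {
  cat(sprintf("<insert_geometry> total %d nt; core %d-%d\n", x$total_len,
              x$core_span[["start"]], x$core_span[["end"]]))
  for (nm in c("fwd_primer_span", "five_flank_span", "vh_span", "linker_span",
               "vl_span", "three_flank_span", "rev_primer_span"))
    cat(sprintf("  %-17s %5d-%5d\n", sub("_span$", "", nm),
                x[[nm]][["start"]], x[[nm]][["end"]]))
  invisible(x)
}

#' Serialize / read an insert geometry as JSON
#' @param g an `insert_geometry`.
#' @param path file path.
#' @return `read_geometry_json` returns an `insert_geometry`.
#' @export
write_geometry_json <- function(g, path) {
  jsonlite::write_json(unclass(g), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- lapply(raw, function(x) {
    if (length(x) == 2) iv(x[1], x[2]) else as.integer(x)
  })
  class(g) <- "insert_geometry"
  validate_geometry(g)
}
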