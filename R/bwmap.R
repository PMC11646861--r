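#' Ballesteros-Weinstein residue numbering map
#'
#' Generic GPCR residue labels of the form `"X.50"` anchor each
#' transmembrane helix at its most conserved position; within a segment the
#' position part increments by one per residue. A map holds the labelled TM
#' segments (each a contiguous residue range with one anchor) plus optional
#' unanchored loop segments (ICL1-3, ECL1-3).
#'
#' @param segments data.frame with columns `segment` (e.g. `"TM6"`,
#'   `"ICL3"`), `start`, `end` (residue range, inclusive), `anchor_label`
#'   (e.g. `"6.48"`, `NA` for loops), `anchor_residue` (`NA` for loops).
#' @return object of class `"bwmap"`.
#' @export
bw_map <- function(segments) {
  stopifnot(is.data.frame(segments),
            all(c("segment", "start", "end", "anchor_label",
                  "anchor_residue") %in% names(segments)))
  stopifnot(all(segments$end >= segments$start))
  anch <- segments[!is.na(segments$anchor_label), , drop = FALSE]
  if (anyDuplicated(anch$anchor_label)) stop("BW anchor labels must be unique")
  ok <- anch$anchor_residue >= anch$start & anch$anchor_residue <= anch$end
  if (!all(ok)) stop("anchors must lie inside their segment")
  structure(list(segments = segments), class = "bwmap")
}

#' Read a BW map from a TSV file
#'
#' Expected columns (tab-separated, with header):
#' `segment  start  end  anchor_label  anchor_residue`.
#' A partial anchor map for the human bitter receptor TAS2R46 (TM3, TM5,
#' TM6, TM7; approximate segment spans) ships as
#' `system.file("extdata", "tas2r46_bw.tsv", package = "allonet")`.
#'
#' @param path TSV file path.
#' @return a [bw_map()].
#' @export
read_bw_map <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(anchor_label = "character"))
  bw_map(d)
}

split_bw_label <- function(label) {
  parts <- strsplit(label, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("malformed BW label: ", label)
  list(tm = as.integer(parts[1]), pos = as.integer(parts[2]))
}

#' Look up the residue carrying a BW label
#'
#' @param map a [bw_map()].
#' @param label BW label string such as `"6.48"`.
#' @return the residue index (integer).
#' @export
bw_lookup <- function(map, label) {
  lb <- split_bw_label(label)
  seg <- map$segments[map$segments$segment == paste0("TM", lb$tm) &
                        !is.na(map$segments$anchor_label), , drop = FALSE]
  if (nrow(seg) == 0) stop("BW lookup error: no mapped segment for ", label)
  seg <- seg[1, ]
  apos <- split_bw_label(seg$anchor_label)$pos
  resid <- seg$anchor_residue + (lb$pos - apos)
  if (resid < seg$start || resid > seg$end) {
    stop("BW lookup error: ", label, " falls outside segment ", seg$segment)
  }
  as.integer(resid)
}

#' Inverse BW lookup: label a residue
#'
#' @param map a [bw_map()].
#' @param resid residue index.
#' @return BW label string for residues inside an anchored TM segment, the
#'   loop segment name for residues inside a loop segment, else `"loop"`.
#' @export
bw_label <- function(map, resid) {
  s <- map$segments
  hit <- which(s$start <= resid & s$end >= resid)
  if (length(hit) == 0) return("loop")
  seg <- s[hit[1], ]
  if (is.na(seg$anchor_label)) return(seg$segment)
  a <- split_bw_label(seg$anchor_label)
  sprintf("%d.%d", a$tm, a$pos + (resid - seg$anchor_residue))
}

#' Residues belonging to a named segment
#'
#' @param map a [bw_map()].
#' @param segment segment name, e.g. `"TM3"`.
#' @return integer vector of residue indices.
#' @export
segment_residues <- function(map, segment) {
  s <- map$segments[map$segments$segment == segment, , drop = FALSE]
  if (nrow(s) == 0) stop("unknown segment: ", segment)
  seq.int(s$start[1], s$end[1])
}
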