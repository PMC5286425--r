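# Internal helpers shared across modules.

# Derive a reproducible child seed from a master seed and a stage label.
# Simple documented counter scheme: children are master*1000 + offset, folded
# into the 32-bit signed range.
child_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  as.integer((abs(seed) * 1009 + offset * 9973) %% .Machine$integer.max)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

stop_isopop <- function(msg, class = "isopop_error") {
  rlang::abort(msg, class = class)
}

# Interval algebra on bp intervals delegated to IRanges. Segment tables use
# 1-based positions with length = end - start; intervals are treated as
# half-open [start, end), i.e. IRanges [start, end - 1], so that widths and
# set operations reproduce the end - start convention exactly.
as_iranges <- function(start, end) {
  IRanges::IRanges(start = as.integer(start), end = as.integer(end) - 1L)
}

# Total length of intervals after removing masked stretches.
masked_length <- function(seg_start, seg_end, mask_start, mask_end) {
  if (length(seg_start) == 0) return(0)
  segs <- IRanges::reduce(as_iranges(seg_start, seg_end))
  if (length(mask_start) > 0) {
    mask <- IRanges::reduce(as_iranges(mask_start, mask_end))
    segs <- IRanges::setdiff(segs, mask)
  }
  sum(IRanges::width(segs))
}

`%||%` <- rlang::`%||%`
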