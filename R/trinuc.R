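## Pyrimidine-strand collapse of the 64 trinucleotides: contexts whose
## central base is a purine are replaced by their reverse complement, the
## standard 32-context convention of mutation-signature practice.
trinuc_collapse_map <- local({
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  rc <- vapply(strsplit(chartr("ACGT", "TGCA", all64), "", fixed = TRUE),
               function(x) paste(rev(x), collapse = ""), character(1))
  collapsed <- ifelse(substr(all64, 2, 2) %in% c("C", "T"), all64, rc)
  stats::setNames(collapsed, all64)
})

## Background mutation weights per pyrimidine-strand trinucleotide context.
## C>T-dominant, as in UV-exposed skin: highest at TpC, elevated at CpC,
## low at non-dipyrimidine cytosines; central T weakly mutable and only
## within dipyrimidines.  Documented generator constants, overridable.
default_trinuc_weights <- local({
  b <- c("A", "C", "G", "T")
  ctx <- as.vector(outer(outer(b, c("C", "T"), function(x, y) paste0(x, y)), b, paste0))
  w <- vapply(ctx, function(s) {
    p5 <- substr(s, 1, 1); ce <- substr(s, 2, 2); p3 <- substr(s, 3, 3)
    if (ce == "C") {
      if (p5 == "T") 1.0 else if (p5 == "C") 0.6 else 0.08
    } else {
      if (p5 %in% c("C", "T") || p3 %in% c("C", "T")) 0.15 else 0.03
    }
  }, numeric(1))
  w
})

## Pyrimidine-strand trinucleotide context at 0-based positions `pos` of a
## contig (character vector `chars`).  NA outside [1, len-2] or at Ns.
context_at <- function(chars, pos) {
  ok <- pos >= 1L & pos <= length(chars) - 2L
  ctx <- rep(NA_character_, length(pos))
  p <- pos[ok]
  raw <- paste0(chars[p], chars[p + 1L], chars[p + 2L])
  ctx[ok] <- unname(trinuc_collapse_map[raw])
  ctx
}
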