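# rbind a list of uniform one-or-more-row data.frames; an empty list
# yields the supplied zero-row prototype instead of rbind's NULL/atomic
.rbindRows <- function(rows, prototype) {
    rows <- Filter(Negate(is.null), rows)
    if (!length(rows)) return(prototype)
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    rownames(out) <- NULL
    out
}
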