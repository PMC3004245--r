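# Classed conditions so callers can distinguish failure modes:
#  - uvc_no_object:  nothing mounted / blank frame (stage 1)
#  - uvc_no_crystal: holder present but no fluorescing crystal (stage 2)
#  - uvc_error:      generic pipeline error

stop_uvc <- function(msg, class = "uvc_error", call. = sys.call(-1)) {
  cnd <- structure(
    class = c(class, "uvc_error", "error", "condition"),
    list(message = msg, call = call.)
  )
  stop(cnd)
}

warn_uvc <- function(msg, class = "uvc_warning") {
  cnd <- structure(
    class = c(class, "uvc_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  warning(cnd)
}
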