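.onLoad <- function(libname, pkgname) {
  # keep large tensor buffers in the heap arena (see src/ops.cpp)
  invisible(.cpp_tune_allocator())
}
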