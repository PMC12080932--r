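// RAII guard enabling flush-to-zero / denormals-are-zero for the duration
// of a kernel call. Exponentially decaying fields (concentration tails,
// LB non-equilibrium parts, stale optimizer moments) otherwise underflow
// into denormal range, where x86 FP throughput collapses; at the fields'
// physical scales the flushed values are far below any meaningful signal.
#ifndef THROMBOSIM_FTZ_H
#define THROMBOSIM_FTZ_H

#ifdef __SSE2__
#include <xmmintrin.h>
#include <pmmintrin.h>
struct FtzGuard {
  unsigned int ftz, daz;
  FtzGuard() {
    ftz = _MM_GET_FLUSH_ZERO_MODE();
    daz = _MM_GET_DENORMALS_ZERO_MODE();
    _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
    _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
  }
  ~FtzGuard() {
    _MM_SET_FLUSH_ZERO_MODE(ftz);
    _MM_SET_DENORMALS_ZERO_MODE(daz);
  }
};
#else
struct FtzGuard {};
#endif

#endif
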