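#ifndef SPIKETE_RNG_H
#define SPIKETE_RNG_H

#include <cstdint>

// splitmix64: small, fast, well-distributed generator; gives the package
// platform-independent streams decoupled from R's global RNG state.
struct SplitMix64 {
  uint64_t state;
  explicit SplitMix64(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform double in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in {0, ..., n-1}
  int unif_int(int n) {
    return static_cast<int>(unif() * n);
  }
};

#endif
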