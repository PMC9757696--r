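#ifndef TARGETASM_SEQUTIL_H
#define TARGETASM_SEQUTIL_H

#include <string>
#include <vector>

namespace targetasm {

inline char upbase(char c) {
  return (c >= 'a' && c <= 'z') ? static_cast<char>(c - 32) : c;
}

inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

inline char complement(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

inline std::string to_upper(const char* s) {
  std::string out(s);
  for (auto& c : out) c = upbase(c);
  return out;
}

inline std::string revcomp(const std::string& s) {
  std::string out(s.size(), 'N');
  for (std::size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = complement(s[i]);
  return out;
}

// For every window start s (0-based), window [s, s+k) is N/ambiguity-free
// iff last_bad[s + k - 1] < s, where last_bad[i] is the largest index <= i
// holding a non-ACGT character (-1 if none).
inline std::vector<long> last_bad_index(const std::string& s) {
  std::vector<long> lb(s.size());
  long last = -1;
  for (std::size_t i = 0; i < s.size(); ++i) {
    if (!is_acgt(s[i])) last = static_cast<long>(i);
    lb[i] = last;
  }
  return lb;
}

} // namespace targetasm

#endif
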