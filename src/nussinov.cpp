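#include <Rcpp.h>
#include <vector>
#include <utility>

using namespace Rcpp;

// Render a (nested) pairing vector as dot-bracket. 1-based partners, 0 for
// unpaired; hot path of the reference folder.
// [[Rcpp::export]]
std::string pairing_to_dotbracket(IntegerVector pairing) {
  const int n = pairing.size();
  std::string out(n, '.');
  for (int i = 0; i < n; ++i) {
    if (pairing[i] > i + 1) out[i] = '(';
    else if (pairing[i] > 0) out[i] = ')';
  }
  return out;
}

// Pair list of a dot-bracket string (up to four bracket layers), as an
// Nx2 matrix of 1-based (i, j) with i < j, ordered by i. Assumes balanced
// input; used on engine output that has already been validated.
// [[Rcpp::export]]
IntegerMatrix dotbracket_pairs(std::string s) {
  const char* open = "([{<";
  const char* close = ")]}>";
  std::vector<int> is, js;
  for (int layer = 0; layer < 4; ++layer) {
    std::vector<int> stack;
    for (int p = 0; p < (int) s.size(); ++p) {
      if (s[p] == open[layer]) stack.push_back(p);
      else if (s[p] == close[layer]) {
        is.push_back(stack.back() + 1);
        js.push_back(p + 1);
        stack.pop_back();
      }
    }
  }
  IntegerMatrix out(is.size(), 2);
  // order by i
  std::vector<int> idx(is.size());
  for (size_t q = 0; q < idx.size(); ++q) idx[q] = q;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return is[a] < is[b]; });
  for (size_t q = 0; q < idx.size(); ++q) {
    out(q, 0) = is[idx[q]];
    out(q, 1) = js[idx[q]];
  }
  return out;
}

// Watson-Crick pairs plus GU wobble.
static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// Maximum base-pairing (Nussinov-style) fold with a minimum hairpin loop of
// `min_loop` unpaired bases. Returns a 1-based pairing vector: entry i holds
// the partner of position i, or 0 if unpaired. Traceback is deterministic:
// at each interval, pairing the leftmost position is preferred over leaving
// it unpaired, and among optimal partners the smallest index wins.
// [[Rcpp::export]]
IntegerVector nussinov_pairing(std::string seq, int min_loop = 3) {
  const int n = (int) seq.size();
  IntegerVector pairing(n, 0);
  if (n <= min_loop + 1) return pairing;

  std::vector< std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      const int j = i + span;
      int best = M[i + 1][j];  // position i left unpaired
      for (int t = i + min_loop + 1; t <= j; ++t) {
        if (can_pair(seq[i], seq[t])) {
          const int inner = (t - 1 >= i + 1) ? M[i + 1][t - 1] : 0;
          const int outer = (t + 1 <= j) ? M[t + 1][j] : 0;
          const int v = 1 + inner + outer;
          if (v > best) best = v;
        }
      }
      M[i][j] = best;
    }
  }

  std::vector< std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    const int i = stack.back().first;
    const int j = stack.back().second;
    stack.pop_back();
    if (j - i <= min_loop) continue;
    bool paired = false;
    for (int t = i + min_loop + 1; t <= j; ++t) {
      if (can_pair(seq[i], seq[t])) {
        const int inner = (t - 1 >= i + 1) ? M[i + 1][t - 1] : 0;
        const int outer = (t + 1 <= j) ? M[t + 1][j] : 0;
        if (1 + inner + outer == M[i][j]) {
          pairing[i] = t + 1;
          pairing[t] = i + 1;
          if (t - 1 > i + 1) stack.push_back(std::make_pair(i + 1, t - 1));
          if (t + 1 < j) stack.push_back(std::make_pair(t + 1, j));
          paired = true;
          break;
        }
      }
    }
    if (!paired) stack.push_back(std::make_pair(i + 1, j));
  }
  return pairing;
}
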