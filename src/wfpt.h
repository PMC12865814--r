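#ifndef MSLRL_WFPT_H
#define MSLRL_WFPT_H

double wfpt_lower(double t, double v, double a, double w, double eps);

#endif
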