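# common function words
the
a
an
of
to
and
in
was
is
at
very
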