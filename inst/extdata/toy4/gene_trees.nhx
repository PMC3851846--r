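((X_A[&&NHX:S=A:Ev=Extant],(X_B[&&NHX:S=B:Ev=Extant],(X_Ct[&&NHX:S=C:Ev=Extant])[&&NHX:S=C:Ev=Trans:ts=2])[&&NHX:S=B:Ev=SpecOut:ts=1])[&&NHX:S=e:Ev=Spec],(X_C[&&NHX:S=C:Ev=Extant],X_D[&&NHX:S=D:Ev=Extant])[&&NHX:S=f:Ev=Spec])[&&NHX:S=r:Ev=Spec];
((Y_A[&&NHX:S=A:Ev=Extant],(Y_B[&&NHX:S=B:Ev=Extant],(Y_Ct[&&NHX:S=C:Ev=Extant])[&&NHX:S=C:Ev=Trans:ts=2])[&&NHX:S=B:Ev=SpecOut:ts=1])[&&NHX:S=e:Ev=Spec],(Y_C[&&NHX:S=C:Ev=Extant],[&&NHX:S=D:Ev=Loss:ts=2])[&&NHX:S=f:Ev=Spec])[&&NHX:S=r:Ev=Spec];
(Z_A1[&&NHX:S=A:Ev=Extant],Z_A2[&&NHX:S=A:Ev=Extant])[&&NHX:S=A:Ev=Dup:ts=2];
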