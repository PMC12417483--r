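id,date,channel,text
c01,2023-02-11,internal,the desk clerk was rude and the tone awful
c02,2023-03-02,internal,rude answer at the desk very rude tone
c03,2023-04-19,external,awful tone terrible service desk line
c04,2023-05-30,internal,angry about the rude desk service line
c05,2023-06-14,external,terrible line awful desk tone service
c06,2023-07-01,internal,line at the desk was terrible rude service
c07,2023-08-12,internal,angry at the awful service line tone desk
c08,2023-09-23,external,rude service terrible tone line desk
c09,2023-10-05,internal,awful line angry desk tone rude service
c10,2023-11-16,external,terrible desk service rude line tone
c11,2024-01-21,internal,slow response unclear explanation about surgery delay
c12,2024-02-08,external,surgery delay slow response unclear notice
c13,2024-03-15,internal,unclear discharge explanation slow response delay
c14,2024-04-27,external,delay in surgery response unclear explanation slow
c15,2024-05-09,internal,slow discharge delay unclear response explanation
c16,2024-06-11,internal,surgery explanation delay was slow and unclear response
c17,2024-07-29,external,unclear response slow surgery delay explanation
c18,2024-08-17,internal,discharge delay unclear slow explanation response
c19,2024-09-28,external,slow surgery unclear delay response explanation
c20,2024-13-45,internal,unclear explanation delay slow response discharge
c21,2024-10-30,external,
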