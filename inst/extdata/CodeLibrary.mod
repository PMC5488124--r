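//------------------------- ODE DOMAINS
// START...END directives used to specify a module.
//%START      odeDomains
realDomain t s; t.min=0; t.max=16; t.delta = 0.1;
//%END        odeDomains
//------------------------- flowCalc
//%START    flowCalc
C:t = (F/V)*(Cin-C);
//%END  flowCalc
//------------------------- EXCHANGE CACULATIONS
//%START      exchangeCalc
C1:t = PS/V1*(C2-C1);    // Exchange between two compartments
C2:t = PS/V2*(C1-C2);
//%END        exchangeCalc
//------------------------- REACTION A->B
//%START      reactionCalc
real G = 5 ml/(g*min);   // Const reaction rate.
A:t = -G/V*A;
B:t = G/V*A;
//%END        reactionCalc
//------------------------- MM REACTION A->B
//%START      MMreactionCalc
real KmA =1.0 mM, VmaxA  =2 umol/(g*min); // MM constant and max velocity of rxn
real G(t) ml/(g*min);    // MM reaction rate
G = (VmaxA/(KmA+A));
A:t = -G*(A)/V;
B:t =  G*(A)/V;
//%END       MmreactionCalc
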